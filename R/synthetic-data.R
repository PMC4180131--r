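## Synthetic data with known ground truth: proteomes with planted MYB
## repeats, gene models with controlled exon counts and tandem spacings, and
## overdispersed count matrices with planted size factors. Every downstream
## module is tested against these generators.

## Strict landmarks never mutate; W60/W98-equivalents substitute only within
## their allowed sets (see LANDMARK_RULES_R3).
plant_repeat <- function(kind, sub_rate) {
  cons <- seq_chars(myb_consensus(kind))
  rules <- if (kind == "R2") LANDMARK_RULES_R2 else LANDMARK_RULES_R3
  subs <- character(0)
  for (p in seq_along(cons)) {
    rule <- rules[[as.character(p)]]
    if (!is.null(rule) && length(rule) == 1L) next  # strict landmark
    if (stats::runif(1) >= sub_rate) next
    if (!is.null(rule)) {
      repl <- sample(setdiff(rule, cons[p]), 1L)
    } else {
      w <- AA_BACKGROUND
      w[cons[p]] <- 0
      repl <- sample(AA_ALPHABET, 1L, prob = w / sum(w))
    }
    subs <- c(subs, sprintf("%d:%s>%s", p, cons[p], repl))
    cons[p] <- repl
  }
  list(seq = paste(cons, collapse = ""), subs = paste(subs, collapse = ";"))
}

random_background_seq <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = AA_BACKGROUND),
        collapse = "")
}

## Repeat architectures per family class. MYB3R carries an R1-like repeat
## (modelled on the R3 consensus) upstream of the R2-R3 pair.
CLASS_ARCHITECTURE <- list(
  r2r3   = c("R2", "R3"),
  myb3r  = c("R1-like", "R2", "R3"),
  myb4r  = c("R2", "R3", "R2", "R3"),
  single = "R2"
)

#' Generate a synthetic proteome with planted MYB repeats
#'
#' Builds proteins as random background flanks around consecutively planted
#' repeat copies of the seed consensus, mutated at per-position rate
#' `sub_rate`. Strict tryptophan landmarks never mutate; the W60- and
#' W98-equivalent landmarks substitute only within their allowed sets
#' (F/I/L/Y and F/C respectively). Decoys are drawn from the background
#' residue distribution. Deterministic given `seed`.
#'
#' @param n_r2r3,n_myb3r,n_myb4r,n_single,n_decoy Protein counts per class
#'   (>= 0).
#' @param sub_rate Per-position substitution probability, `0 <= sub_rate < 0.5`.
#' @param seed Integer RNG seed.
#' @param flank_range Min/max random flank length on each side.
#' @param decoy_length_range Min/max decoy protein length.
#' @return List with `proteome` (named character vector of sequences) and
#'   `truth` (class `synthetic_truth`; `$protein_truth` maps protein id to a
#'   `data.frame` of planted repeats: `start`, `end`, `repeat_kind`,
#'   `substitutions`).
#' @export
generate_proteome <- function(n_r2r3 = 0, n_myb3r = 0, n_myb4r = 0,
                              n_single = 0, n_decoy = 0, sub_rate = 0,
                              seed = 1, flank_range = c(20, 80),
                              decoy_length_range = c(200, 400)) {
  counts <- c(r2r3 = n_r2r3, myb3r = n_myb3r, myb4r = n_myb4r,
              single = n_single, decoy = n_decoy)
  if (any(counts < 0)) stop("protein counts must be >= 0", call. = FALSE)
  if (sub_rate < 0 || sub_rate >= 0.5) {
    stop("`sub_rate` must be in [0, 0.5)", call. = FALSE)
  }
  with_seed(seed, {
    seqs <- character(0)
    truth <- list()
    for (cls in names(CLASS_ARCHITECTURE)) {
      for (i in seq_len(counts[[cls]])) {
        id <- sprintf("%s_%03d", cls, i)
        left <- sample(flank_range[1]:flank_range[2], 1L)
        right <- sample(flank_range[1]:flank_range[2], 1L)
        kinds <- CLASS_ARCHITECTURE[[cls]]
        planted <- lapply(kinds, function(k) {
          plant_repeat(if (k == "R1-like") "R3" else k, sub_rate)
        })
        widths <- vapply(planted, function(p) nchar(p$seq), integer(1))
        starts <- left + 1L + cumsum(c(0L, widths[-length(widths)]))
        seqs[[id]] <- paste0(
          random_background_seq(left),
          paste(vapply(planted, `[[`, character(1), "seq"), collapse = ""),
          random_background_seq(right)
        )
        truth[[id]] <- data.frame(
          start = as.integer(starts),
          end = as.integer(starts + widths - 1L),
          repeat_kind = kinds,
          substitutions = vapply(planted, `[[`, character(1), "subs"),
          stringsAsFactors = FALSE
        )
      }
    }
    for (i in seq_len(counts[["decoy"]])) {
      id <- sprintf("decoy_%03d", i)
      len <- sample(decoy_length_range[1]:decoy_length_range[2], 1L)
      seqs[[id]] <- random_background_seq(len)
      truth[[id]] <- data.frame(
        start = integer(0), end = integer(0), repeat_kind = character(0),
        substitutions = character(0), stringsAsFactors = FALSE
      )
    }
    list(
      proteome = seqs,
      truth = structure(list(protein_truth = truth, seed = seed),
                        class = "synthetic_truth")
    )
  })
}

#' Random gene-model layout
#'
#' Draws non-overlapping gene starts on the given chromosomes; a convenience
#' input for [generate_gene_models()].
#'
#' @param n_genes Number of genes.
#' @param chromosomes Chromosome labels to draw from.
#' @param chr_length Coordinate space per chromosome.
#' @param exon_range Min/max exon count per gene.
#' @param seed Integer RNG seed.
#' @return Layout `data.frame` (`gene_id`, `chromosome`, `start`, `exon_n`,
#'   `strand`).
#' @export
random_gene_layout <- function(n_genes, chromosomes = c("chr1", "chr2"),
                               chr_length = 1e6, exon_range = c(1, 5),
                               seed = 1) {
  with_seed(seed, {
    repeat {
      layout <- data.frame(
        gene_id = sprintf("gene_%03d", seq_len(n_genes)),
        chromosome = sample(chromosomes, n_genes, replace = TRUE),
        start = sample.int(as.integer(chr_length), n_genes),
        exon_n = sample(exon_range[1]:exon_range[2], n_genes, replace = TRUE),
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        stringsAsFactors = FALSE
      )
      bodies <- gene_body_lengths(layout$exon_n)
      ok <- TRUE
      for (chr in unique(layout$chromosome)) {
        sub <- layout[layout$chromosome == chr, , drop = FALSE]
        b <- bodies[layout$chromosome == chr]
        o <- order(sub$start)
        s <- sub$start[o]; e <- s + b[o] - 1L
        if (any(s[-1] <= e[-length(e)])) { ok <- FALSE; break }
      }
      if (ok) break
    }
    layout[order(layout$chromosome, layout$start), , drop = FALSE]
  })
}

EXON_LEN <- 150L
INTRON_LEN <- 200L

gene_body_lengths <- function(exon_n) {
  as.integer(exon_n * EXON_LEN + pmax(exon_n - 1L, 0L) * INTRON_LEN)
}

#' Generate synthetic gene models as GFF3
#'
#' Lays out gene/mRNA/exon features (1-based inclusive coordinates) from a
#' layout table. Exons are `150` bp with `200` bp introns, so the gene body
#' length is a deterministic function of the exon count. Requested gene bodies
#' that overlap on one chromosome are an error. Output text is byte-stable for
#' a given layout.
#'
#' @param layout `data.frame` with columns `gene_id`, `chromosome`, `start`,
#'   `exon_n` and optionally `strand` (default alternating).
#' @param tandem_max Start-to-start spacing (bp) at or below which two
#'   same-chromosome genes are recorded as a tandem pair in the truth.
#' @return List with `gff3` (character vector of GFF3 lines) and `truth`
#'   (class `synthetic_truth`; `$gene_truth` has per-gene `chromosome`,
#'   `exon_n`, `tandem_partner`).
#' @export
generate_gene_models <- function(layout, tandem_max = 105000) {
  req <- c("gene_id", "chromosome", "start", "exon_n")
  if (!all(req %in% names(layout))) {
    stop("layout needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(layout$exon_n < 1L)) stop("exon_n must be >= 1", call. = FALSE)
  if (is.null(layout$strand)) {
    layout$strand <- rep(c("+", "-"), length.out = nrow(layout))
  }
  layout <- layout[order(layout$chromosome, layout$start), , drop = FALSE]
  body <- gene_body_lengths(layout$exon_n)
  layout$end <- layout$start + body - 1L
  for (chr in unique(layout$chromosome)) {
    sub <- layout[layout$chromosome == chr, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      stop("overlapping gene bodies requested on ", chr, call. = FALSE)
    }
  }
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(layout))) {
    g <- layout[i, ]
    lines <- c(lines, sprintf(
      "%s\tmybfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chromosome, g$start, g$end, g$strand, g$gene_id
    ), sprintf(
      "%s\tmybfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
      g$chromosome, g$start, g$end, g$strand, g$gene_id, g$gene_id
    ))
    ex_start <- g$start + (seq_len(g$exon_n) - 1L) * (EXON_LEN + INTRON_LEN)
    for (j in seq_len(g$exon_n)) {
      lines <- c(lines, sprintf(
        "%s\tmybfam\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
        g$chromosome, ex_start[j], ex_start[j] + EXON_LEN - 1L, g$strand,
        g$gene_id, j, g$gene_id
      ))
    }
  }
  partner <- rep(NA_character_, nrow(layout))
  for (i in seq_len(nrow(layout))) {
    same <- which(layout$chromosome == layout$chromosome[i] &
                    seq_len(nrow(layout)) != i &
                    abs(layout$start - layout$start[i]) <= tandem_max)
    if (length(same)) partner[i] <- layout$gene_id[same[1]]
  }
  truth <- data.frame(
    gene_id = layout$gene_id, chromosome = layout$chromosome,
    exon_n = as.integer(layout$exon_n), tandem_partner = partner,
    stringsAsFactors = FALSE
  )
  list(
    gff3 = lines,
    truth = structure(list(gene_truth = truth), class = "synthetic_truth")
  )
}

#' Generate a synthetic organ x gene count matrix with planted size factors
#'
#' Per-gene base means are drawn log-uniformly, organ-restricted genes are
#' zeroed according to the planted presence pattern, and counts are drawn
#' from a negative binomial with mean `base_mean * scale_factor` and the
#' given dispersion (matching the overdispersed structure RNA-seq
#' normalisation assumes). Deterministic given `seed`.
#'
#' @param n_genes Number of genes.
#' @param samples Character vector of organ/sample names.
#' @param scale_factors One strictly positive factor per sample.
#' @param seed Integer RNG seed.
#' @param base_mean_range Range of per-gene base means (log-uniform draw).
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param prop_restricted Fraction of genes given an organ-restricted
#'   presence pattern (expressed in a random non-empty subset of organs).
#' @param prop_silent Fraction of genes silenced in every organ.
#' @return List with `counts` (integer matrix, genes x samples) and `truth`
#'   (class `synthetic_truth`; `$expression_truth` holds `scale_factors`,
#'   `presence_pattern` (logical genes x samples), `base_means`).
#' @export
generate_counts <- function(n_genes, samples, scale_factors, seed = 1,
                            base_mean_range = c(20, 500), dispersion = 0.05,
                            prop_restricted = 0, prop_silent = 0) {
  if (length(scale_factors) != length(samples)) {
    stop("need one scale factor per sample", call. = FALSE)
  }
  if (any(scale_factors <= 0)) {
    stop("scale factors must be strictly positive", call. = FALSE)
  }
  with_seed(seed, {
    mu <- exp(stats::runif(n_genes, log(base_mean_range[1]),
                           log(base_mean_range[2])))
    pattern <- matrix(TRUE, n_genes, length(samples),
                      dimnames = list(sprintf("gene_%04d", seq_len(n_genes)),
                                      samples))
    n_restricted <- round(prop_restricted * n_genes)
    n_silent <- round(prop_silent * n_genes)
    special <- sample.int(n_genes, n_restricted + n_silent)
    for (g in special[seq_len(n_restricted)]) {
      on <- sample(length(samples), sample(seq_len(length(samples) - 1L), 1L))
      pattern[g, -on] <- FALSE
    }
    if (n_silent > 0) {
      pattern[special[n_restricted + seq_len(n_silent)], ] <- FALSE
    }
    counts <- matrix(0L, n_genes, length(samples),
                     dimnames = dimnames(pattern))
    for (s in seq_along(samples)) {
      lam <- mu * scale_factors[s]
      draw <- stats::rnbinom(n_genes, mu = lam, size = 1 / dispersion)
      draw[!pattern[, s]] <- 0L
      counts[, s] <- as.integer(draw)
    }
    truth <- structure(
      list(expression_truth = list(
        scale_factors = stats::setNames(scale_factors, samples),
        presence_pattern = pattern,
        base_means = mu
      ), seed = seed),
      class = "synthetic_truth"
    )
    list(counts = counts, truth = truth)
  })
}

#' Write a proteome to FASTA (60-column wrap)
#' @param proteome Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  x <- Biostrings::AAStringSet(unlist(proteome))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write generated GFF3 lines to a file
#' @param gff3 Character vector of GFF3 lines (from [generate_gene_models()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gff3, path) {
  writeLines(gff3, path)
  invisible(path)
}

#' Write a count matrix as TSV (genes x samples, header row of sample names)
#' @param counts Integer matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth record as JSON
#' @param truth A `synthetic_truth` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
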