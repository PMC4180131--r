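## Genomic characterisation of the family: gene models from GFF3,
## chromosomal distribution, tandem sister-gene pairs, exon-structure
## categories and family-level summary percentages.

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features into one record per gene. Coordinates are
#' normalized so `start <= end` regardless of strand (the original
#' orientation is kept in `strand`); exon intervals are attached per gene via
#' the `Parent` chain. Genes without exon children fall back to the gene body
#' as a single exon, with a warning.
#'
#' @param path GFF3 file path.
#' @return `data.frame` of class `gene_models`: `gene_id`, `chromosome`,
#'   `strand`, `start`, `end`, `exon_n`, plus an `exons` list-column of
#'   two-column start/end matrices.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (nrow(df) == 0L) return(empty_gene_models())
  type <- as.character(df$type)
  get_id <- function(i) as.character(df$ID[i])
  genes <- df[type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) return(empty_gene_models())
  ## map transcript id -> gene id
  tx <- df[type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_parent <- stats::setNames(
    vapply(tx$Parent, function(p) as.character(p)[1], character(1)),
    as.character(tx$ID)
  )
  exons <- df[type == "exon", , drop = FALSE]
  exon_gene <- vapply(exons$Parent, function(p) {
    p <- as.character(p)[1]
    if (p %in% names(tx_parent)) tx_parent[[p]] else p
  }, character(1))
  out <- data.frame(
    gene_id = as.character(genes$ID),
    chromosome = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    start = pmin(genes$start, genes$end),
    end = pmax(genes$start, genes$end),
    stringsAsFactors = FALSE
  )
  ex_list <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    sel <- exon_gene == out$gene_id[i]
    if (!any(sel)) {
      warning("gene ", out$gene_id[i],
              " has no exon children; using the gene body", call. = FALSE)
      ex_list[[i]] <- cbind(start = out$start[i], end = out$end[i])
    } else {
      m <- cbind(start = pmin(exons$start[sel], exons$end[sel]),
                 end = pmax(exons$start[sel], exons$end[sel]))
      ex_list[[i]] <- m[order(m[, 1]), , drop = FALSE]
    }
  }
  out$exon_n <- vapply(ex_list, nrow, integer(1))
  out$exons <- ex_list
  class(out) <- c("gene_models", class(out))
  out
}

empty_gene_models <- function() {
  out <- data.frame(
    gene_id = character(0), chromosome = character(0), strand = character(0),
    start = integer(0), end = integer(0), exon_n = integer(0),
    stringsAsFactors = FALSE
  )
  out$exons <- list()
  class(out) <- c("gene_models", class(out))
  out
}

#' Read the packaged B. vulgaris MYB family catalogue fixture
#'
#' A transcription of the published catalogue of the 75 multi-repeat
#' B. vulgaris MYB genes: identifier, chromosomal assignment and
#' pseudochromosome coordinates, clade/subgroup, landmark MYBs, functional
#' assignment, protein length, exon count and family class. Chromosome
#' labels follow the source convention: a bare digit is a placed gene, a
#' digit + `un` is assigned to the chromosome without position, and `rnd`
#' labels are unanchored scaffolds. Coordinates are printed in transcript
#' orientation; use `start`/`end` as printed and normalize downstream.
#'
#' @param path Optional alternative TSV with the same columns.
#' @return `data.frame` with 75 rows.
#' @export
read_family_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bvmyb_table1.tsv", package = "mybfam")
  }
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chromosome = "character"))
}

#' Exon-structure category of a gene
#'
#' @param exon_n Integer vector of exon counts.
#' @return Character vector with levels `"1"`, `"2"`, `"3"`, `">3"`.
#' @export
exon_category <- function(exon_n) {
  if (any(exon_n < 1L)) stop("exon counts must be >= 1", call. = FALSE)
  ifelse(exon_n > 3L, ">3", as.character(exon_n))
}

## "5un" counts toward chromosome 5; "rnd*" scaffolds are unanchored.
chromosome_of <- function(label) {
  ifelse(grepl("^rnd", label), "unanchored", sub("un$", "", label))
}

#' Per-chromosome counts of family genes
#'
#' Genes assigned to a chromosome without position (`un` suffix) count toward
#' that chromosome; unanchored scaffolds (`rnd` labels) are aggregated into
#' an `unanchored` bucket. When chromosome lengths are supplied, the density
#' is reported both as genes per Mb and as Mb per gene.
#'
#' @param genes `data.frame` with `chromosome` (raw label) and optionally
#'   `family_class`.
#' @param class_filter Restrict to one family class (e.g. `"R2R3"`), or
#'   `NULL` for all.
#' @param chr_lengths Optional named vector of chromosome lengths in bp.
#' @return `data.frame` with `chromosome`, `count` and, when lengths are
#'   given, `genes_per_mb`, `mb_per_gene`.
#' @export
chromosome_distribution <- function(genes, class_filter = NULL,
                                    chr_lengths = NULL) {
  if (!is.null(class_filter)) {
    genes <- genes[genes$family_class %in% class_filter, , drop = FALSE]
  }
  chrom <- chromosome_of(genes$chromosome)
  tab <- table(chrom)
  out <- data.frame(
    chromosome = names(tab), count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  ## numeric chromosomes first, unanchored last
  suppressWarnings(num <- as.numeric(out$chromosome))
  out <- out[order(is.na(num), num), , drop = FALSE]
  if (!is.null(chr_lengths)) {
    len <- chr_lengths[out$chromosome]
    out$genes_per_mb <- out$count / (len / 1e6)
    out$mb_per_gene <- (len / 1e6) / out$count
  }
  rownames(out) <- NULL
  out
}

#' Detect tandem sister-gene pairs
#'
#' All pairs of genes sharing a chromosome/scaffold label whose normalized
#' start-to-start distance (minimum coordinate of each gene, so the measure
#' is strand-independent) is at most `max_distance`. With
#' `require_no_intervening = TRUE` and a full gene `annotation`, pairs with
#' an annotated gene between them are dropped. Each unordered pair is
#' reported once, sorted by chromosome then coordinate.
#'
#' @param genes `data.frame` with `gene_id`, `chromosome`, `start`, `end`.
#' @param max_distance Distance threshold in bp (default 105000).
#' @param require_no_intervening Drop pairs with intervening annotated genes.
#' @param annotation Optional full gene set (same columns) used for the
#'   intervening-gene check.
#' @return `data.frame` with `gene_a`, `gene_b`, `chromosome`, `distance`,
#'   and `intervening_genes` when an annotation was supplied.
#' @export
detect_sister_pairs <- function(genes, max_distance = 105000,
                                require_no_intervening = FALSE,
                                annotation = NULL) {
  if (max_distance <= 0) stop("`max_distance` must be > 0", call. = FALSE)
  pos <- pmin(genes$start, genes$end)
  n <- nrow(genes)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (genes$chromosome[i] != genes$chromosome[j]) next
        d <- abs(pos[i] - pos[j])
        if (d > max_distance) next
        o <- order(c(pos[i], pos[j]))
        ids <- c(genes$gene_id[i], genes$gene_id[j])[o]
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = ids[1], gene_b = ids[2],
          chromosome = genes$chromosome[i],
          distance = d, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene_a = character(0), gene_b = character(0), chromosome = character(0),
    distance = numeric(0), stringsAsFactors = FALSE
  )
  if (!is.null(annotation)) {
    ann_pos <- pmin(annotation$start, annotation$end)
    out$intervening_genes <- vapply(seq_len(nrow(out)), function(k) {
      a <- out$gene_a[k]; b <- out$gene_b[k]
      pa <- pos[match(a, genes$gene_id)]
      pb <- pos[match(b, genes$gene_id)]
      lo <- min(pa, pb); hi <- max(pa, pb)
      sum(annotation$chromosome == out$chromosome[k] &
            ann_pos > lo & ann_pos < hi &
            !(annotation$gene_id %in% c(a, b)))
    }, numeric(1))
    if (require_no_intervening) {
      out <- out[out$intervening_genes == 0, , drop = FALSE]
    }
  }
  out <- out[order(out$chromosome, out$distance, out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Family-level summary percentages
#'
#' The family's share of the predicted proteome (rounded to 2 decimals) and
#' of the transcription-factor complement (rounded to 1 decimal), both in
#' percent.
#'
#' @param n_family Number of family genes.
#' @param n_proteome Number of predicted protein-coding genes.
#' @param n_tf Number of putative transcription-factor genes.
#' @return Named list `pct_proteome`, `pct_tf`.
#' @export
family_statistics <- function(n_family, n_proteome, n_tf) {
  if (n_proteome <= 0 || n_tf <= 0) {
    stop("denominators must be > 0", call. = FALSE)
  }
  list(
    pct_proteome = round(100 * n_family / n_proteome, 2),
    pct_tf = round(100 * n_family / n_tf, 1)
  )
}
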