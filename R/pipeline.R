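## End-to-end orchestration: synthetic-bundle or file inputs through repeat
## scanning, classification, conservation, motif annotation, genome context
## and expression, into a family catalogue plus a summary report.

#' Read a flat key=value pipeline configuration
#'
#' One `key = value` per line, `#` comments; comma-separated values become
#' vectors and numeric-looking values are converted.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    suppressWarnings(num <- as.numeric(parts))
    cfg[[key]] <- if (!anyNA(num)) num else parts
  }
  cfg
}

#' Run the family-analysis pipeline on a synthetic bundle
#'
#' Executes the stages in dependency order: generate (or read) the proteome,
#' scan and classify every protein, profile repeat conservation, annotate
#' motifs and diagnostic residues, lay out gene models for the family
#' members, detect sister pairs, and (optionally) generate and summarise an
#' expression matrix. All randomness flows from `config$seed`; a config
#' without a seed is rejected when stochastic stages run. Stage progress is
#' logged to stderr.
#'
#' @param config Named list (or path to a key=value file readable by
#'   [read_pipeline_config()]). Recognised keys: `seed` (required),
#'   `n_r2r3`, `n_myb3r`, `n_myb4r`, `n_single`, `n_decoy`, `sub_rate`
#'   (proteome generation); `expression` (logical, default `TRUE`),
#'   `samples`, `scale_factors` (expression generation); `out_dir`
#'   (optional: write catalogue/report files there).
#' @return List of class `myb_pipeline_result`: `catalogue` (one row per
#'   multi-repeat family member), `summary` (from [summary_statistics()]),
#'   `classification`, `truth`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  defaults <- list(
    n_r2r3 = 20, n_myb3r = 2, n_myb4r = 1, n_single = 3, n_decoy = 20,
    sub_rate = 0.03, expression = TRUE,
    samples = c("seedling", "taproot", "young_leaf", "old_leaf",
                "inflorescence", "seed"),
    scale_factors = c(4.02, 1.25, 3.53, 0.11, 1.47, 0.41)
  )
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) {
    stop("config must provide a `seed` for the stochastic stages",
         call. = FALSE)
  }
  seed <- as.integer(cfg$seed)
  log_stage <- function(...) message("[mybfam] ", sprintf(...))

  log_stage("stage proteome: generating synthetic proteome (seed %d)", seed)
  prot <- generate_proteome(
    n_r2r3 = cfg$n_r2r3, n_myb3r = cfg$n_myb3r, n_myb4r = cfg$n_myb4r,
    n_single = cfg$n_single, n_decoy = cfg$n_decoy,
    sub_rate = cfg$sub_rate, seed = seed
  )

  log_stage("stage scan: profile scan + family classification")
  profiles <- default_myb_profiles()
  cls <- classify_proteome(prot$proteome, profiles)
  family <- cls$table[cls$table$n_repeats >= 2L, , drop = FALSE]

  log_stage("stage conservation: repeat frequency matrices")
  r2_windows <- character(0); r3_windows <- character(0)
  domains <- list()
  for (id in family$protein_id) {
    c1 <- cls$classifications[[id]]
    hits <- c1$repeats
    chars <- seq_chars(prot$proteome[[id]])
    for (k in seq_len(nrow(hits))) {
      win <- paste(chars[hits$start[k]:hits$end[k]], collapse = "")
      if (hits$repeat_kind[k] == "R2") r2_windows <- c(r2_windows, win)
      if (hits$repeat_kind[k] == "R3") r3_windows <- c(r3_windows, win)
    }
    if (c1$family_class == "R2R3") {
      domains[[id]] <- extract_domain(c1, prot$proteome[[id]])
    }
  }
  conservation <- list(
    R2 = if (length(r2_windows) >= 1L) {
      position_frequencies(align_repeats(r2_windows, "R2"))
    },
    R3 = if (length(r3_windows) >= 1L) {
      position_frequencies(align_repeats(r3_windows, "R3"))
    }
  )

  log_stage("stage motifs: motif and diagnostic-residue annotation")
  motifs <- myb_motifs()
  bhlh <- vapply(family$protein_id, function(id) {
    nrow(scan_motif(prot$proteome[[id]], motifs$bhlh)) > 0L
  }, logical(1))
  sg7_2 <- vapply(family$protein_id, function(id) {
    hit <- scan_sg7_terminal(prot$proteome[[id]])
    if (is.null(hit)) NA_character_ else hit$tier
  }, character(1))
  res89 <- vapply(family$protein_id, function(id) {
    if (is.null(domains[[id]])) return(NA_character_)
    residue_diagnostics(domains[[id]])$res89
  }, character(1))

  log_stage("stage genome: gene models + sister pairs")
  n_fam <- nrow(family)
  layout <- random_gene_layout(
    n_fam, chromosomes = paste0("chr", 1:3), chr_length = 5e6,
    exon_range = c(1, 4), seed = seed + 1L
  )
  layout$gene_id <- family$protein_id  # join proteins to gene models
  gm <- generate_gene_models(layout)
  genes <- data.frame(
    gene_id = layout$gene_id, chromosome = layout$chromosome,
    start = layout$start, end = layout$start + 1L,
    stringsAsFactors = FALSE
  )
  pairs <- detect_sister_pairs(genes)

  catalogue <- data.frame(
    gene_id = family$protein_id,
    family_class = family$family_class,
    n_repeats = family$n_repeats,
    chromosome = layout$chromosome[match(family$protein_id, layout$gene_id)],
    start = layout$start[match(family$protein_id, layout$gene_id)],
    exon_n = layout$exon_n[match(family$protein_id, layout$gene_id)],
    protein_length = nchar(unlist(prot$proteome[family$protein_id])),
    bhlh_motif = bhlh,
    sg7_2_tier = sg7_2,
    res89 = res89,
    stringsAsFactors = FALSE,
    row.names = NULL
  )

  expression <- NULL
  if (isTRUE(as.logical(cfg$expression[1]))) {
    log_stage("stage expression: counts, size factors, presence calls")
    gen <- generate_counts(
      n_fam, samples = cfg$samples, scale_factors = cfg$scale_factors,
      seed = seed + 2L, prop_restricted = 0.1, prop_silent = 0.05
    )
    rownames(gen$counts) <- family$protein_id
    sf <- size_factors(gen$counts)
    nmz <- normalize_counts(gen$counts, sf)
    pres <- presence_calls(nmz)
    expression <- list(counts = gen$counts, size_factors = sf,
                       normalized = nmz, presence = pres,
                       truth = gen$truth)
    catalogue$expressed_organs <- rowSums(pres$presence)
  } else {
    log_stage("stage expression: omitted by config")
  }

  summary <- summary_statistics(
    catalogue,
    n_proteome = length(prot$proteome),
    n_tf = max(nrow(family), 1L)
  )
  structure(
    list(catalogue = catalogue, summary = summary, classification = cls,
         conservation = conservation, gene_models = gm, sister_pairs = pairs,
         expression = expression, truth = prot$truth, config = cfg),
    class = "myb_pipeline_result"
  )
}

#' @export
print.myb_pipeline_result <- function(x, ...) {
  cat(sprintf("<myb_pipeline_result> %d family members\n", nrow(x$catalogue)))
  print(x$summary$class_counts)
  invisible(x)
}

#' Family-level summary statistics from a catalogue
#'
#' Everything is recomputed from the catalogue rows: family-class counts,
#' per-chromosome counts, the exon-category histogram over R2R3 members,
#' sister pairs (when coordinates are present) and the proteome/TF share
#' percentages.
#'
#' @param catalogue `data.frame` with at least `family_class`; `chromosome`,
#'   `exon_n`, `start`/`end` and motif columns are used when present.
#' @param n_proteome,n_tf Denominators for [family_statistics()].
#' @param max_pair_distance Sister-pair threshold in bp.
#' @return List with `n_family`, `class_counts`, `chromosome_counts`,
#'   `exon_histogram`, `sister_pairs`, `pct_proteome`, `pct_tf`, and
#'   `n_bhlh_positive` when the catalogue has a `bhlh_motif` column.
#' @export
summary_statistics <- function(catalogue, n_proteome, n_tf,
                               max_pair_distance = 105000) {
  if (is.null(catalogue) || nrow(catalogue) == 0L) {
    stop("empty catalogue", call. = FALSE)
  }
  class_counts <- table(factor(
    catalogue$family_class,
    levels = c("R2R3", "MYB3R", "MYB4R", "CDC5-like")
  ))
  out <- list(
    n_family = nrow(catalogue),
    class_counts = class_counts
  )
  if (!is.null(catalogue$chromosome)) {
    out$chromosome_counts <- chromosome_distribution(catalogue)
  }
  if (!is.null(catalogue$exon_n)) {
    r2r3 <- catalogue[catalogue$family_class == "R2R3", , drop = FALSE]
    out$exon_histogram <- table(factor(exon_category(r2r3$exon_n),
                                       levels = c("1", "2", "3", ">3")))
  }
  if (!is.null(catalogue$start)) {
    genes <- data.frame(
      gene_id = catalogue$gene_id, chromosome = catalogue$chromosome,
      start = catalogue$start,
      end = if (!is.null(catalogue$end)) catalogue$end else catalogue$start,
      stringsAsFactors = FALSE
    )
    out$sister_pairs <- detect_sister_pairs(genes, max_pair_distance)
  }
  fs <- family_statistics(nrow(catalogue), n_proteome, n_tf)
  out$pct_proteome <- fs$pct_proteome
  out$pct_tf <- fs$pct_tf
  if (!is.null(catalogue$bhlh_motif)) {
    out$n_bhlh_positive <- sum(catalogue$bhlh_motif, na.rm = TRUE)
  }
  out
}

#' Write a pipeline report (text + JSON)
#'
#' @param result A `myb_pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- result$summary
  txt <- c(
    "# MYB family analysis report",
    sprintf("seed = %s", result$config$seed),
    sprintf("sub_rate = %s", result$config$sub_rate),
    sprintf("family members: %d", s$n_family),
    sprintf("class counts: %s",
            paste(names(s$class_counts), as.integer(s$class_counts),
                  sep = "=", collapse = ", ")),
    sprintf("pct of proteome: %.2f%%; pct of TFs: %.1f%%",
            s$pct_proteome, s$pct_tf),
    sprintf("sister pairs: %d",
            if (is.null(s$sister_pairs)) 0L else nrow(s$sister_pairs))
  )
  txt_path <- file.path(out_dir, "report.txt")
  writeLines(txt, txt_path)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(
      seed = result$config$seed,
      n_family = s$n_family,
      class_counts = as.list(s$class_counts),
      pct_proteome = s$pct_proteome,
      pct_tf = s$pct_tf,
      n_sister_pairs = if (is.null(s$sister_pairs)) 0L
                       else nrow(s$sister_pairs)
    ),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  cat_path <- file.path(out_dir, "catalogue.tsv")
  utils::write.table(result$catalogue, cat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(txt_path, json_path, cat_path))
}
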