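## Organ-expression characterisation from a count matrix: median-of-ratios
## size factors, normalisation, presence calls and centroid-linkage
## clustering of log2 values.

#' Read a counts TSV (genes x samples)
#'
#' First column = gene identifiers, header row = sample (organ) names.
#'
#' @param path TSV file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Median-of-ratios size factors
#'
#' The per-sample scaling constants of the median-of-ratios method: the
#' reference for each gene is its geometric mean across samples (genes with
#' a zero anywhere are excluded), and a sample's factor is the median over
#' those genes of count/reference. This is the estimator popularised by the
#' DESeq family of tools; the test suite cross-checks against
#' `DESeq2::estimateSizeFactorsForMatrix()`, which agrees up to its
#' log-scale median interpolation on even gene counts.
#'
#' @param cm Count matrix (genes x samples), non-negative.
#' @return Named numeric vector of strictly positive factors.
#' @export
size_factors <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0)) stop("counts must be non-negative", call. = FALSE)
  if (ncol(cm) < 1L) stop("need at least one sample", call. = FALSE)
  all_pos <- rowSums(cm > 0) == ncol(cm)
  if (!any(all_pos)) {
    stop("every gene has a zero count in some sample; median-of-ratios is ",
         "undefined - consider a pseudo-reference (e.g. add 1 to all counts)",
         call. = FALSE)
  }
  ref <- exp(rowMeans(log(cm[all_pos, , drop = FALSE])))
  sf <- apply(cm[all_pos, , drop = FALSE] / ref, 2, stats::median)
  stats::setNames(as.numeric(sf), colnames(cm))
}

#' Normalise counts by size factors
#'
#' @param cm Count matrix (genes x samples).
#' @param sf Size factors from [size_factors()]; must cover every sample.
#' @return Numeric matrix `counts[g, s] / sf[s]`.
#' @export
normalize_counts <- function(cm, sf = size_factors(cm)) {
  cm <- as.matrix(cm)
  if (length(sf) != ncol(cm)) {
    stop("one size factor per sample required", call. = FALSE)
  }
  if (!is.null(names(sf)) && !is.null(colnames(cm))) {
    if (!setequal(names(sf), colnames(cm))) {
      stop("size factor names do not match sample names", call. = FALSE)
    }
    sf <- sf[colnames(cm)]
  }
  sweep(cm, 2, sf, `/`)
}

#' Presence calls and organ tallies
#'
#' A gene is called present in an organ when its normalized value exceeds
#' `threshold` (default 0: any detected expression counts).
#'
#' @param nm Normalized matrix (genes x samples).
#' @param threshold Non-negative presence cutoff.
#' @return List of class `presence_calls`: `presence` (logical matrix),
#'   `threshold`, `per_organ` (named counts), `in_all`, `in_any`, `nowhere`.
#' @export
presence_calls <- function(nm, threshold = 0) {
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  pres <- nm > threshold
  structure(
    list(
      presence = pres,
      threshold = threshold,
      per_organ = colSums(pres),
      in_all = sum(rowSums(pres) == ncol(pres)),
      in_any = sum(rowSums(pres) > 0),
      nowhere = sum(rowSums(pres) == 0)
    ),
    class = "presence_calls"
  )
}

#' @export
print.presence_calls <- function(x, ...) {
  cat(sprintf(
    "<presence_calls> threshold=%g: %d in any organ, %d in all, %d nowhere\n",
    x$threshold, x$in_any, x$in_all, x$nowhere
  ))
  invisible(x)
}

#' Centroid-linkage hierarchical clustering of expression profiles
#'
#' Log2-transforms the normalized values (`log2(x + pseudo)`) and
#' agglomerates genes by centroid linkage under Euclidean distance
#' ([stats::hclust()] `method = "centroid"` on squared distances; merge
#' heights are squared Euclidean and may be non-monotone, which is inherent
#' to centroid linkage). A single gene returns the identity ordering.
#'
#' @param nm Normalized matrix (genes x samples).
#' @param pseudo Positive pseudo-count added before the log (default 1).
#' @return List with `order` (row indices in dendrogram order), `labels`,
#'   `merge`, `height`, `hclust` (the full object, `NULL` for n < 2), and
#'   `logmat` (the transformed matrix).
#' @export
cluster_genes <- function(nm, pseudo = 1) {
  if (pseudo <= 0) stop("`pseudo` must be positive", call. = FALSE)
  lm2 <- log2(nm + pseudo)
  n <- nrow(lm2)
  if (n < 2L) {
    return(list(order = seq_len(n), labels = rownames(nm),
                merge = NULL, height = NULL, hclust = NULL, logmat = lm2))
  }
  d2 <- stats::dist(lm2)^2
  hc <- stats::hclust(d2, method = "centroid")
  list(order = hc$order, labels = rownames(nm), merge = hc$merge,
       height = hc$height, hclust = hc, logmat = lm2)
}

#' Export clustered heatmap data
#'
#' Reorders the log2 matrix by the clustering leaf order and writes the
#' table a heatmap renderer needs. The intended colour mapping is black at 0
#' (no detected expression) through increasing intensity of yellow.
#'
#' @param nm Normalized matrix.
#' @param clustering Result of [cluster_genes()] on `nm` (or `NULL` to keep
#'   the input order).
#' @param path Optional TSV output path.
#' @param pseudo Pseudo-count matching the clustering transform.
#' @return `data.frame`: `gene_id` plus one log2 column per sample, rows in
#'   leaf order.
#' @export
export_heatmap <- function(nm, clustering = NULL, path = NULL, pseudo = 1) {
  lm2 <- if (!is.null(clustering)) clustering$logmat else log2(nm + pseudo)
  ord <- if (!is.null(clustering)) clustering$order else seq_len(nrow(nm))
  out <- data.frame(
    gene_id = rownames(nm)[ord],
    lm2[ord, , drop = FALSE],
    check.names = FALSE, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
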