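## Repeat-domain conservation profiling: per-position residue frequencies
## over aligned repeat windows (sequence-logo data) and conservation-class
## calls. Fixed-width repeat windows share coordinates by construction, so
## alignment is landmark-anchored column stacking rather than a general MSA.

#' Stack repeat windows of one kind into an aligned block
#'
#' All repeats must come from the same kind (R2 or R3) and therefore share
#' width and coordinates; the "alignment" is the column-wise stack.
#'
#' @param repeats Character vector of repeat window sequences.
#' @param kind Repeat kind of every sequence (`"R2"` or `"R3"`), used for the
#'   canonical position offset (R2 starts at canonical 1, R3 at 54).
#' @return Object of class `repeat_block`: character matrix (sequences x
#'   positions) with the canonical positions as column names.
#' @export
align_repeats <- function(repeats, kind = c("R2", "R3")) {
  kind <- match.arg(kind)
  seqs <- toupper(as.character(repeats))
  if (length(seqs) == 0L) stop("no repeat sequences given", call. = FALSE)
  widths <- unique(nchar(seqs))
  if (length(widths) != 1L) {
    stop("mixed repeat kinds or ragged widths: all sequences of one kind ",
         "share a fixed width", call. = FALSE)
  }
  expected <- nchar(myb_consensus(kind))
  if (widths != expected) {
    stop(sprintf("%s repeats are %d positions wide, got %d",
                 kind, expected, widths), call. = FALSE)
  }
  offset <- if (kind == "R2") R2_CANONICAL_OFFSET else R3_CANONICAL_OFFSET
  m <- do.call(rbind, lapply(seqs, seq_chars))
  colnames(m) <- as.character(seq_len(widths) + offset)
  rownames(m) <- names(seqs)
  structure(m, class = c("repeat_block", class(m)), kind = kind)
}

#' Per-position residue frequencies and information content
#'
#' Frequencies by direct tally with gaps (`-`, `.`, `X`) excluded from the
#' denominator; information content per position is `log2(20) - H(position)`
#' in bits, with no small-sample correction.
#'
#' @param block A `repeat_block` from [align_repeats()] (or any character
#'   matrix of residues with positions as columns).
#' @return Object of class `frequency_matrix`: list with `positions`
#'   (canonical indices), `freq` (position x residue matrix, rows sum to 1),
#'   `information` (bits per position), `n_sequences`.
#' @export
position_frequencies <- function(block) {
  if (is.null(dim(block)) || nrow(block) == 0L) {
    stop("empty alignment block", call. = FALSE)
  }
  positions <- as.integer(colnames(block))
  if (anyNA(positions)) positions <- seq_len(ncol(block))
  freq <- t(apply(block, 2, function(col) {
    col <- col[col %in% AA_ALPHABET]
    if (length(col) == 0L) return(stats::setNames(rep(0, 20), AA_ALPHABET))
    tab <- tabulate(factor(col, levels = AA_ALPHABET), nbins = 20L)
    stats::setNames(tab / sum(tab), AA_ALPHABET)
  }))
  info <- apply(freq, 1, function(f) {
    f <- f[f > 0]
    log2(20) - sum(-f * log2(f))
  })
  structure(
    list(positions = positions, freq = freq,
         information = as.numeric(info), n_sequences = nrow(block)),
    class = "frequency_matrix"
  )
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("<frequency_matrix> %d positions, %d sequences\n",
              length(x$positions), x$n_sequences))
  invisible(x)
}

#' Conservation-class calls per position
#'
#' A position is `invariant` when its modal residue has frequency 1,
#' `highly_conserved` when the modal frequency is at least `high_cutoff`
#' (but below 1), otherwise `variable`.
#'
#' @param fm A `frequency_matrix`.
#' @param high_cutoff High-conservation cutoff, `0.5 < high_cutoff < 1`
#'   (default 0.9).
#' @return `data.frame` sorted by position: `position`, `class`,
#'   `modal_residue`, `modal_frequency`.
#' @export
conservation_calls <- function(fm, high_cutoff = 0.9) {
  stopifnot(inherits(fm, "frequency_matrix"))
  if (high_cutoff <= 0.5 || high_cutoff >= 1) {
    stop("`high_cutoff` must be in (0.5, 1)", call. = FALSE)
  }
  modal_i <- apply(fm$freq, 1, which.max)
  modal_f <- fm$freq[cbind(seq_len(nrow(fm$freq)), modal_i)]
  cls <- ifelse(modal_f >= 1, "invariant",
                ifelse(modal_f >= high_cutoff, "highly_conserved", "variable"))
  out <- data.frame(
    position = fm$positions,
    class = cls,
    modal_residue = colnames(fm$freq)[modal_i],
    modal_frequency = as.numeric(modal_f),
    stringsAsFactors = FALSE
  )
  out[order(out$position), , drop = FALSE]
}

#' Sequence-logo stack heights
#'
#' Stack height of residue `a` at position `p` is
#' `frequency(p, a) * information(p)`, the quantity a logo renderer draws.
#'
#' @param fm A `frequency_matrix`.
#' @param path Optional file; when given, the table is written as TSV.
#' @return `data.frame` in long format: `position`, `residue`, `frequency`,
#'   `information`, `stack_height` (zero-frequency rows omitted).
#' @export
export_logo_data <- function(fm, path = NULL) {
  stopifnot(inherits(fm, "frequency_matrix"))
  rows <- which(fm$freq > 0, arr.ind = TRUE)
  out <- data.frame(
    position = fm$positions[rows[, 1]],
    residue = colnames(fm$freq)[rows[, 2]],
    frequency = fm$freq[rows],
    information = fm$information[rows[, 1]],
    stringsAsFactors = FALSE
  )
  out$stack_height <- out$frequency * out$information
  out <- out[order(out$position, -out$frequency, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
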