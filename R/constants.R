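#' @keywords internal
"_PACKAGE"

## Standard 20-letter amino-acid alphabet, fixed column order used by every
## frequency/score matrix in the package.
AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

## Background amino-acid frequencies (average protein composition, Robinson &
## Robinson-style values), renormalised to sum exactly to 1. Used for decoy
## generation, profile log-odds and scoring of ambiguous residues.
AA_BACKGROUND <- local({
  f <- c(
    A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
    Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
    L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
    S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.066
  )
  f[AA_ALPHABET] / sum(f)
})

#' Amino-acid background frequencies
#'
#' The background residue distribution used throughout the package: decoy
#' proteins are sampled from it, profile log-odds scores are taken against it,
#' and `X` residues score as background (log-odds 0).
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() AA_BACKGROUND

## Run code under a temporary RNG state so generators are deterministic
## without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Split a protein string into a character vector of residues.
seq_chars <- function(x) strsplit(toupper(as.character(x)), "")[[1]]

#' Protein length implied by an open reading frame
#'
#' Number of residues encoded by an ORF of `orf_bp` base pairs, counting the
#' stop codon as untranslated: `orf_bp / 3 - 1`.
#'
#' @param orf_bp ORF length in base pairs, including the stop codon. Must be a
#'   positive multiple of 3.
#' @return Integer protein length in residues.
#' @examples
#' orf_protein_length(1164) # 387
#' @export
orf_protein_length <- function(orf_bp) {
  if (any(orf_bp <= 0) || any(orf_bp %% 3 != 0)) {
    stop("`orf_bp` must be a positive multiple of 3", call. = FALSE)
  }
  as.integer(orf_bp / 3 - 1)
}
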