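## MYB repeat detection via position-specific scoring profiles.
##
## The MYB DNA-binding domain consists of imperfect ~52-residue repeats, each
## carrying three regularly spaced tryptophans that form the hydrophobic core
## of a helix-turn-helix. The scanner slides a fixed-width log-odds profile
## (one per repeat kind) over a protein, keeps windows that clear a
## null-calibrated score threshold AND satisfy the tryptophan landmark rules,
## and resolves overlaps greedily by descending score.

#' Canonical repeat numbering
#'
#' The combined R2R3 domain is numbered 1-104: the R2 repeat covers canonical
#' positions 1-53 and the R3 repeat (including the linker context) covers
#' 54-104. Tryptophan landmarks sit at canonical 7/26/45 (R2) and 60/79/98
#' (R3); within the R3 repeat window these are local positions 7/26/45.
#'
#' @name canonical-numbering
#' @keywords internal
NULL

R2_CANONICAL_OFFSET <- 0L   # canonical position = local position
R3_CANONICAL_OFFSET <- 53L  # canonical position = local position + 53

## Landmark rules: local window position -> allowed residues. The first
## residue of each set is the canonical one; any other allowed residue is
## recorded as a substitution. W60 tolerates F/I/L/Y and W98 tolerates F/C;
## all other landmark tryptophans are strict.
LANDMARK_RULES_R2 <- list(`7` = "W", `26` = "W", `45` = "W")
LANDMARK_RULES_R3 <- list(
  `7`  = c("W", "F", "I", "L", "Y"),
  `26` = "W",
  `45` = c("W", "F", "C")
)

#' Consensus MYB repeat sequences used by the synthetic seed model
#'
#' Returns the consensus sequence of the packaged synthetic seed alignment for
#' one repeat kind. These consensi carry the canonical landmark architecture
#' (tryptophans at local positions 7/26/45) and the invariant/highly-conserved
#' residues of the plant R2R3-MYB domain (e.g. D11, C43, R46 in R2; E64, G76,
#' R89, T90 in R3, canonical numbering), but are synthetic stand-ins, not a
#' published consensus; replace the seed alignment to rebuild profiles from
#' your own repeats.
#'
#' @param kind `"R2"` or `"R3"`.
#' @return A single character string (53 residues for R2, 51 for R3).
#' @export
myb_consensus <- function(kind = c("R2", "R3")) {
  kind <- match.arg(kind)
  if (kind == "R2") {
    "LNKGAVWSKEDNELISYIKAHGEGKWRSLPKRAGGLQRCGKSCRWRLINYLRP"
  } else {
    "DVKNYVWSPEEDEILVAHQKYGGNKWSEIAKLLPGRTDNEIKNHWNSTLKR"
  }
}

#' Build a position-specific scoring profile from aligned seed repeats
#'
#' Per position and residue the log-odds score is
#' `log((count + pseudocount * background) / (n + pseudocount)) - log(background)`,
#' i.e. a pseudocount-smoothed estimate of the column frequency against the
#' background distribution.
#'
#' @param seed_repeats Character vector (or `AAStringSet`) of aligned,
#'   equal-length repeat sequences; at least 2.
#' @param pseudocount Positive smoothing constant (default 1).
#' @param kind Repeat kind label attached to hits, `"R2"` or `"R3"`.
#' @param landmark_rules Named list mapping local window position to the
#'   allowed residue set; defaults to the canonical tryptophan rules for
#'   `kind`.
#' @param background Residue background frequencies (default
#'   [aa_background()]).
#' @param threshold Minimum window score for a hit; leave `NULL` and call
#'   [calibrate_threshold()] (or use [default_myb_profiles()]) to set it from
#'   the empirical null.
#' @return An object of class `myb_profile`: list with `length`, `scores`
#'   (position x residue log-odds matrix, natural log), `background`,
#'   `landmark_rules`, `threshold`, `kind`, `consensus`.
#' @export
build_profile <- function(seed_repeats, pseudocount = 1, kind = c("R2", "R3"),
                          landmark_rules = NULL,
                          background = aa_background(), threshold = NULL) {
  kind <- match.arg(kind)
  seqs <- toupper(as.character(seed_repeats))
  if (length(seqs) < 2L) stop("need at least 2 seed sequences", call. = FALSE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("seed alignment is ragged: sequence widths differ", call. = FALSE)
  }
  plen <- widths[1]
  if (pseudocount <= 0) stop("`pseudocount` must be positive", call. = FALSE)
  mat <- do.call(rbind, lapply(seqs, seq_chars))
  n <- nrow(mat)
  counts <- apply(mat, 2, function(col) {
    tabulate(factor(col, levels = AA_ALPHABET), nbins = 20L)
  })  # 20 x plen
  bg <- background[AA_ALPHABET]
  scores <- log((counts + pseudocount * bg) / (n + pseudocount)) - log(bg)
  scores <- t(scores)  # plen x 20
  colnames(scores) <- AA_ALPHABET
  consensus <- paste(AA_ALPHABET[apply(counts, 2, which.max)], collapse = "")
  if (is.null(landmark_rules)) {
    landmark_rules <- if (kind == "R2") LANDMARK_RULES_R2 else LANDMARK_RULES_R3
  }
  structure(
    list(
      length = as.integer(plen),
      scores = scores,
      background = bg,
      landmark_rules = landmark_rules,
      threshold = threshold,
      kind = kind,
      consensus = consensus,
      n_seed = n,
      pseudocount = pseudocount
    ),
    class = "myb_profile"
  )
}

#' @export
print.myb_profile <- function(x, ...) {
  cat(sprintf(
    "<myb_profile> kind=%s length=%d seed_n=%d threshold=%s\n",
    x$kind, x$length, x$n_seed,
    if (is.null(x$threshold)) "unset" else sprintf("%.2f", x$threshold)
  ))
  invisible(x)
}

## Map a residue vector to alphabet indices; unknown letters (X etc.) -> NA,
## which scores as background (log-odds 0).
aa_index <- function(chars) match(chars, AA_ALPHABET)

## Score every window offset of an index vector against a profile.
## Returns numeric(n_windows); empty when the sequence is shorter than the
## profile.
window_scores <- function(idx, profile) {
  plen <- profile$length
  n_win <- length(idx) - plen + 1L
  if (n_win < 1L) return(numeric(0))
  acc <- numeric(n_win)
  sc <- profile$scores
  for (k in seq_len(plen)) {
    s <- sc[k, ][idx[k:(k + n_win - 1L)]]
    s[is.na(s)] <- 0
    acc <- acc + s
  }
  acc
}

## Check landmark rules for windows starting at `starts` (1-based offsets into
## `chars`). Returns logical vector.
landmarks_ok <- function(chars, starts, profile) {
  ok <- rep(TRUE, length(starts))
  for (p in names(profile$landmark_rules)) {
    pos <- as.integer(p)
    allowed <- profile$landmark_rules[[p]]
    ok <- ok & chars[starts + pos - 1L] %in% allowed
  }
  ok
}

## Describe the landmark residues of one window, e.g. "7=W;26=W;45=F*"
## (asterisk marks an allowed substitution away from the canonical residue).
landmark_evidence <- function(chars, start, profile) {
  parts <- vapply(names(profile$landmark_rules), function(p) {
    pos <- as.integer(p)
    allowed <- profile$landmark_rules[[p]]
    res <- chars[start + pos - 1L]
    sprintf("%s=%s%s", p, res, if (res != allowed[1]) "*" else "")
  }, character(1))
  paste(parts, collapse = ";")
}

#' Calibrate the hit threshold from an empirical null
#'
#' Generates `n_decoys` random proteins from the profile's background residue
#' distribution, records the maximum window score of each, and sets the
#' threshold to the `quantile` quantile (default 99.9%) of that null max-score
#' distribution.
#'
#' @param profile A `myb_profile`.
#' @param n_decoys Number of null proteins (default 1000).
#' @param decoy_length Length of each null protein (default 300).
#' @param quantile Null quantile used as threshold (default 0.999).
#' @param seed RNG seed for the null sample.
#' @return The profile with `threshold` set; the null max scores are attached
#'   as attribute `null_max_scores`.
#' @export
calibrate_threshold <- function(profile, n_decoys = 1000, decoy_length = 300,
                                quantile = 0.999, seed = 1) {
  stopifnot(inherits(profile, "myb_profile"))
  maxima <- with_seed(seed, {
    vapply(seq_len(n_decoys), function(i) {
      idx <- sample.int(20L, decoy_length, replace = TRUE,
                        prob = profile$background)
      max(window_scores(idx, profile))
    }, numeric(1))
  })
  profile$threshold <- as.numeric(stats::quantile(maxima, quantile, type = 1))
  attr(profile, "null_max_scores") <- maxima
  profile
}

## Package-level cache for the default profile pair.
.mybfam_cache <- new.env(parent = emptyenv())

#' Default R2/R3 scoring profiles
#'
#' Builds the R2 and R3 profiles from the packaged synthetic seed alignments
#' and calibrates their thresholds against a fixed-seed empirical null (99.9th
#' percentile of the null max-window score over 1000 background decoys). The
#' result is cached for the session, so repeated calls are cheap and
#' deterministic.
#'
#' @param recompute Force a rebuild, ignoring the cache.
#' @return Named list with elements `R2` and `R3`, each a `myb_profile`.
#' @export
default_myb_profiles <- function(recompute = FALSE) {
  if (!recompute && !is.null(.mybfam_cache$profiles)) {
    return(.mybfam_cache$profiles)
  }
  r2_path <- system.file("extdata", "seed_r2_synthetic.afa", package = "mybfam")
  r3_path <- system.file("extdata", "seed_r3_synthetic.afa", package = "mybfam")
  r2_seed <- as.character(Biostrings::readAAStringSet(r2_path))
  r3_seed <- as.character(Biostrings::readAAStringSet(r3_path))
  r2 <- calibrate_threshold(build_profile(r2_seed, kind = "R2"), seed = 104)
  r3 <- calibrate_threshold(build_profile(r3_seed, kind = "R3"), seed = 105)
  .mybfam_cache$profiles <- list(R2 = r2, R3 = r3)
  .mybfam_cache$profiles
}

## Greedy overlap resolution: descending score, ties by leftmost start (and
## stable input order beyond that). `cand` is a data.frame with start/end/score.
resolve_overlaps <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  ord <- order(-cand$score, cand$start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    clash <- any(s <= occupied[, 2] & e >= occupied[, 1])
    if (!clash) {
      keep[i] <- TRUE
      occupied <- rbind(occupied, c(s, e))
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Scan a protein with one repeat profile
#'
#' Slides the profile over every offset; windows scoring at or above the
#' profile threshold and satisfying the landmark rules become candidate hits.
#' Overlapping candidates are resolved greedily by descending score (ties to
#' the leftmost start). A sequence shorter than the profile yields zero hits.
#'
#' @param protein Protein sequence (character string or `AAString`).
#' @param profile A `myb_profile` with a set threshold.
#' @param id Protein identifier recorded in the hits.
#' @return `data.frame` with columns `protein_id`, `start`, `end` (1-based
#'   inclusive), `score`, `repeat_kind`, `landmark_evidence`, sorted by
#'   `start`.
#' @export
scan_protein <- function(protein, profile, id = "protein") {
  stopifnot(inherits(profile, "myb_profile"))
  if (is.null(profile$threshold)) {
    stop("profile threshold is unset; calibrate it first", call. = FALSE)
  }
  chars <- seq_chars(protein)
  if (length(chars) == 0L) stop("empty protein sequence", call. = FALSE)
  idx <- aa_index(chars)
  sc <- window_scores(idx, profile)
  hits0 <- empty_hits()
  if (length(sc) == 0L) return(hits0)
  starts <- which(sc >= profile$threshold)
  if (length(starts) == 0L) return(hits0)
  starts <- starts[landmarks_ok(chars, starts, profile)]
  if (length(starts) == 0L) return(hits0)
  cand <- data.frame(
    protein_id = id,
    start = starts,
    end = starts + profile$length - 1L,
    score = sc[starts],
    repeat_kind = profile$kind,
    landmark_evidence = vapply(
      starts, function(s) landmark_evidence(chars, s, profile), character(1)
    ),
    stringsAsFactors = FALSE
  )
  res <- resolve_overlaps(cand)
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  data.frame(
    protein_id = character(0), start = integer(0), end = integer(0),
    score = numeric(0), repeat_kind = character(0),
    landmark_evidence = character(0), stringsAsFactors = FALSE
  )
}

#' Classify the repeat kind of a window
#'
#' Rescores the window anchored at `start` under both the R2 and the R3
#' profile and returns the kind with the larger mean per-position score. A
#' margin below `tie_tol` (per position) is reported as `"unclassified"`; a
#' profile that does not fit within the sequence scores `-Inf`.
#'
#' @param protein Protein sequence.
#' @param start 1-based window start (from [scan_protein()]).
#' @param profile_r2,profile_r3 The two repeat profiles.
#' @param tie_tol Tie tolerance on the mean per-position score (default 0.05
#'   nats).
#' @return One of `"R2"`, `"R3"`, `"unclassified"`.
#' @export
classify_repeat_kind <- function(protein, start, profile_r2, profile_r3,
                                 tie_tol = 0.05) {
  chars <- seq_chars(protein)
  idx <- aa_index(chars)
  per_pos <- function(profile) {
    if (start + profile$length - 1L > length(idx)) return(-Inf)
    s <- profile$scores
    tot <- 0
    for (k in seq_len(profile$length)) {
      v <- s[k, ][idx[start + k - 1L]]
      tot <- tot + ifelse(is.na(v), 0, v)
    }
    tot / profile$length
  }
  s2 <- per_pos(profile_r2)
  s3 <- per_pos(profile_r3)
  if (is.infinite(s2) && is.infinite(s3)) return("unclassified")
  if (abs(s2 - s3) < tie_tol) return("unclassified")
  if (s2 > s3) "R2" else "R3"
}

#' Scan a protein with both repeat profiles and label repeat kinds
#'
#' Pools candidate windows from the R2 and R3 profiles, resolves overlaps
#' jointly (greedy, descending score, ties to the leftmost start), relabels
#' each surviving hit by [classify_repeat_kind()], and finally marks a repeat
#' immediately upstream of an R2-R3 pair in a >= 3-repeat protein as
#' `"R1-like"`.
#'
#' @inheritParams scan_protein
#' @param profiles List with elements `R2` and `R3` (default
#'   [default_myb_profiles()]).
#' @param tie_tol Passed to [classify_repeat_kind()].
#' @return Hit `data.frame` as in [scan_protein()], sorted by `start`.
#' @export
scan_myb_repeats <- function(protein, profiles = default_myb_profiles(),
                             id = "protein", tie_tol = 0.05) {
  chars <- seq_chars(protein)
  cand <- rbind(
    candidate_hits(chars, profiles$R2, id),
    candidate_hits(chars, profiles$R3, id)
  )
  hits <- resolve_overlaps(cand)
  if (nrow(hits) == 0L) {
    rownames(hits) <- NULL
    return(hits)
  }
  hits$repeat_kind <- vapply(hits$start, function(s) {
    classify_repeat_kind(protein, s, profiles$R2, profiles$R3, tie_tol)
  }, character(1))
  ## R1-like: the repeat directly upstream of an R2-R3 pair in a multi-repeat
  ## (>= 3) protein, mirroring the R1R2R3 architecture.
  if (nrow(hits) >= 3L) {
    for (i in seq_len(nrow(hits) - 1L)) {
      if (i >= 2L && hits$repeat_kind[i] == "R2" &&
          hits$repeat_kind[i + 1L] == "R3") {
        hits$repeat_kind[i - 1L] <- "R1-like"
      }
    }
  }
  rownames(hits) <- NULL
  hits
}

## Candidate windows (threshold + landmarks, no overlap resolution).
candidate_hits <- function(chars, profile, id) {
  if (is.null(profile$threshold)) {
    stop("profile threshold is unset; calibrate it first", call. = FALSE)
  }
  idx <- aa_index(chars)
  sc <- window_scores(idx, profile)
  if (length(sc) == 0L) return(empty_hits())
  starts <- which(sc >= profile$threshold)
  starts <- starts[landmarks_ok(chars, starts, profile)]
  if (length(starts) == 0L) return(empty_hits())
  data.frame(
    protein_id = id,
    start = starts,
    end = starts + profile$length - 1L,
    score = sc[starts],
    repeat_kind = profile$kind,
    landmark_evidence = vapply(
      starts, function(s) landmark_evidence(chars, s, profile), character(1)
    ),
    stringsAsFactors = FALSE
  )
}

#' Classify a protein into a MYB family class from its repeat hits
#'
#' Repeat count maps to class: 0 hits = `non-MYB`, 1 = `single-repeat`
#' (excluded from the multi-repeat family set), 2 = `R2R3`, 3 = `MYB3R`,
#' >= 4 = `MYB4R`. A multi-repeat protein whose full-length global-alignment
#' identity to the CDC5 landmark exceeds `cdc5_cutoff` is reclassified
#' `CDC5-like` regardless of count.
#'
#' @param hits Hit `data.frame` from [scan_myb_repeats()] for this protein.
#' @param protein Protein sequence (needed for the CDC5 check; may be omitted
#'   when `cdc5_landmark` is `NULL`).
#' @param id Protein identifier.
#' @param cdc5_landmark Optional CDC5 reference protein sequence.
#' @param cdc5_cutoff Identity cutoff in percent for the CDC5 override
#'   (default 40; global alignment, BLOSUM62, affine gaps 10/1).
#' @return Object of class `myb_classification`: list with `protein_id`,
#'   `family_class`, `n_repeats`, `repeats` (the hits).
#' @export
classify_protein <- function(hits, protein = NULL, id = "protein",
                             cdc5_landmark = NULL, cdc5_cutoff = 40) {
  n <- nrow(hits)
  class_ <- if (n == 0L) "non-MYB"
  else if (n == 1L) "single-repeat"
  else if (n == 2L) "R2R3"
  else if (n == 3L) "MYB3R"
  else "MYB4R"
  if (n >= 2L && !is.null(cdc5_landmark) && !is.null(protein)) {
    pid <- global_identity(protein, cdc5_landmark)
    if (pid > cdc5_cutoff) class_ <- "CDC5-like"
  }
  structure(
    list(protein_id = id, family_class = class_, n_repeats = n,
         repeats = hits),
    class = "myb_classification"
  )
}

#' @export
print.myb_classification <- function(x, ...) {
  cat(sprintf("<myb_classification> %s: %s (%d repeat%s)\n",
              x$protein_id, x$family_class, x$n_repeats,
              if (x$n_repeats == 1L) "" else "s"))
  invisible(x)
}

## Percent identity of a global (Needleman-Wunsch) alignment, BLOSUM62,
## affine gap penalties 10 (open) / 1 (extend).
global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(as.character(a))),
    Biostrings::AAString(toupper(as.character(b))),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1
  )
  Biostrings::pid(aln)
}

#' Extract the canonically numbered R2R3 domain
#'
#' Maps the R2 and R3 repeat windows of an R2R3-classified protein onto
#' canonical positions 1-104 (R2 = 1-53, R3 = 54-104; the linker between the
#' windows, if any, falls outside profile coverage and is not part of the
#' canonical map).
#'
#' @param classification A `myb_classification` with `family_class == "R2R3"`.
#' @param protein The protein sequence the hits refer to.
#' @return List with `domain` (104-residue string), `map` (`data.frame` of
#'   `canonical` position and `protein` coordinate), `protein_id`.
#' @export
extract_domain <- function(classification, protein) {
  stopifnot(inherits(classification, "myb_classification"))
  if (classification$family_class != "R2R3") {
    stop("extract_domain() requires an R2R3-classified protein", call. = FALSE)
  }
  hits <- classification$repeats
  r2 <- hits[hits$repeat_kind == "R2", , drop = FALSE]
  r3 <- hits[hits$repeat_kind == "R3", , drop = FALSE]
  if (nrow(r2) != 1L || nrow(r3) != 1L) {
    stop("expected exactly one R2 and one R3 repeat hit", call. = FALSE)
  }
  chars <- seq_chars(protein)
  prot_coord <- c(r2$start + 0:52, r3$start + 0:50)
  map <- data.frame(canonical = 1:104, protein = as.integer(prot_coord))
  list(
    domain = paste(chars[prot_coord], collapse = ""),
    map = map,
    protein_id = classification$protein_id
  )
}

#' Classify every protein of a proteome
#'
#' Convenience wrapper: runs [scan_myb_repeats()] and [classify_protein()]
#' over a named set of sequences.
#'
#' @param proteome Named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @param profiles Profile pair (default [default_myb_profiles()]).
#' @param cdc5_landmark,cdc5_cutoff Passed to [classify_protein()].
#' @return List with `classifications` (list of `myb_classification`) and
#'   `table` (`data.frame` of `protein_id`, `family_class`, `n_repeats`).
#' @export
classify_proteome <- function(proteome, profiles = default_myb_profiles(),
                              cdc5_landmark = NULL, cdc5_cutoff = 40) {
  seqs <- as.character(proteome)
  if (!is.null(names(proteome))) names(seqs) <- names(proteome)
  if (is.null(names(seqs))) names(seqs) <- paste0("protein", seq_along(seqs))
  cls <- lapply(names(seqs), function(id) {
    hits <- scan_myb_repeats(seqs[[id]], profiles, id = id)
    classify_protein(hits, seqs[[id]], id = id,
                     cdc5_landmark = cdc5_landmark, cdc5_cutoff = cdc5_cutoff)
  })
  names(cls) <- names(seqs)
  tab <- data.frame(
    protein_id = names(seqs),
    family_class = vapply(cls, `[[`, character(1), "family_class"),
    n_repeats = vapply(cls, `[[`, integer(1), "n_repeats"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(classifications = cls, table = tab)
}
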