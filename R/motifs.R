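## Functional motif annotation: the bHLH-interaction motif of the R3 repeat,
## the C-terminal SG7/SG7-2 flavonol-regulator motifs, and the diagnostic
## residues at canonical domain positions 44, 60, 89 and 98.

#' Parse a Prosite-style motif pattern
#'
#' Grammar: a single residue letter matches itself; `[ABC]` matches any
#' residue of the set; `x` is a wildcard; a digit run after `x` repeats the
#' wildcard exactly that many times (`x2` = two wildcards). A bracket set
#' containing `x` (e.g. `[Wx]`) is treated as a wildcard for mismatch
#' counting but keeps its preferred residues for tier scoring.
#'
#' @param name Motif name.
#' @param pattern Pattern string, e.g. `"[DE]Lx2[RK]x3Lx6Lx3R"`.
#' @param region `"whole"` or `"cterm"` (search only the C-terminal window).
#' @param max_mismatch Default mismatch tolerance at fixed positions.
#' @param cterm_window Width of the C-terminal search window when
#'   `region = "cterm"`.
#' @return Object of class `motif_pattern` with `elements` (list of allowed
#'   sets; `NULL` = wildcard), `width`, plus the call parameters.
#' @export
motif_pattern <- function(name, pattern, region = c("whole", "cterm"),
                          max_mismatch = 0, cterm_window = 30) {
  region <- match.arg(region)
  elements <- list()
  preferred <- list()
  i <- 1L
  chars <- seq_chars(pattern)
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars[-seq_len(i)] == "]")[1] + i
      if (is.na(j)) stop("unclosed bracket in pattern", call. = FALSE)
      set <- setdiff(chars[(i + 1L):(j - 1L)], c(",", "/"))
      if ("X" %in% set) {
        elements <- c(elements, list(NULL))  # wildcard for matching
        preferred <- c(preferred, list(setdiff(set, "X")))
      } else {
        elements <- c(elements, list(set))
        preferred <- c(preferred, list(set))
      }
      i <- j + 1L
    } else if (ch == "X") {
      i <- i + 1L
      reps <- 1L
      digs <- character(0)
      while (i <= n && chars[i] %in% as.character(0:9)) {
        digs <- c(digs, chars[i]); i <- i + 1L
      }
      if (length(digs)) reps <- as.integer(paste(digs, collapse = ""))
      for (k in seq_len(reps)) {
        elements <- c(elements, list(NULL))
        preferred <- c(preferred, list(character(0)))
      }
    } else if (ch %in% AA_ALPHABET) {
      elements <- c(elements, list(ch))
      preferred <- c(preferred, list(ch))
      i <- i + 1L
    } else {
      stop("unexpected character in pattern: ", ch, call. = FALSE)
    }
  }
  structure(
    list(name = name, pattern = pattern, elements = elements,
         preferred = preferred, width = length(elements),
         region = region, max_mismatch = max_mismatch,
         cterm_window = cterm_window),
    class = "motif_pattern"
  )
}

#' Built-in motif patterns
#'
#' * `bhlh`: the bHLH-interaction consensus `[D/E]Lx2[R/K]x3Lx6Lx3R` of the
#'   R3 repeat (width 20, exact wildcard counts, zero mismatches by default).
#' * `sg7`: the subgroup-7 flavonol-regulator motif `GRTxRSxMK`, default
#'   tolerance 2 fixed-position mismatches.
#' * `sg7_loose`: variant reading `GRTxRSxMx` with the final position free,
#'   under which the known one-substitution match differs at a single fixed
#'   position; shipped because the literature's wildcard placement is
#'   ambiguous. Default tolerance 1.
#' * `sg7_2`: the C-terminal `[W/x][L/x]LS` motif (see
#'   [scan_sg7_terminal()] for tiered matching).
#'
#' @return Named list of `motif_pattern` objects.
#' @export
myb_motifs <- function() {
  list(
    bhlh = motif_pattern("bhlh", "[DE]Lx2[RK]x3Lx6Lx3R",
                         region = "whole", max_mismatch = 0),
    sg7 = motif_pattern("sg7", "GRTxRSxMK", region = "cterm",
                        max_mismatch = 2, cterm_window = 50),
    sg7_loose = motif_pattern("sg7_loose", "GRTxRSxMx", region = "cterm",
                              max_mismatch = 1, cterm_window = 50),
    sg7_2 = motif_pattern("sg7_2", "[Wx][Lx]LS", region = "cterm",
                          max_mismatch = 0, cterm_window = 10)
  )
}

#' Scan a protein for a motif pattern
#'
#' Reports every placement (inside the pattern's search region) whose
#' mismatch count at fixed (non-wildcard) positions is at most
#' `max_mismatch`, in left-to-right order.
#'
#' @param protein Protein sequence.
#' @param pattern A `motif_pattern`.
#' @param max_mismatch Mismatch tolerance; defaults to the pattern's own.
#' @param id Protein identifier.
#' @return `data.frame` with `protein_id`, `motif`, `start` (1-based, in
#'   protein coordinates), `match`, `mismatches`.
#' @export
scan_motif <- function(protein, pattern, max_mismatch = pattern$max_mismatch,
                       id = "protein") {
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- seq_chars(protein)
  w <- pattern$width
  empty <- data.frame(protein_id = character(0), motif = character(0),
                      start = integer(0), match = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (length(chars) < w) return(empty)
  region_start <- 1L
  if (pattern$region == "cterm") {
    region_start <- max(1L, length(chars) - pattern$cterm_window + 1L)
  }
  starts <- region_start:(length(chars) - w + 1L)
  if (length(starts) == 0L || starts[1] > starts[length(starts)]) return(empty)
  rows <- lapply(starts, function(s) {
    mm <- 0L
    for (k in seq_len(w)) {
      allowed <- pattern$elements[[k]]
      if (!is.null(allowed) && !(chars[s + k - 1L] %in% allowed)) mm <- mm + 1L
      if (mm > max_mismatch) return(NULL)
    }
    data.frame(
      protein_id = id, motif = pattern$name, start = s,
      match = paste(chars[s:(s + w - 1L)], collapse = ""),
      mismatches = mm, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) empty else out
}

#' Count motif-positive proteins
#'
#' @param proteins Named character vector of protein sequences.
#' @param pattern A `motif_pattern`.
#' @param max_mismatch Mismatch tolerance; defaults to the pattern's own.
#' @return Number of proteins with at least one hit.
#' @export
count_motif_positive <- function(proteins, pattern,
                                 max_mismatch = pattern$max_mismatch) {
  seqs <- as.character(proteins)
  sum(vapply(seqs, function(s) {
    nrow(scan_motif(s, pattern, max_mismatch)) > 0L
  }, logical(1)))
}

#' Tiered SG7-2 search at the C-terminal end
#'
#' Searches the last `window` residues for `x-x-L-S`. The match tier records
#' how well the preferred residues are realised: `base` (only L-S fixed
#' positions), upgraded by W at position 1 and/or L at position 2; `WL` is
#' the top tier (`WLLS`). The most C-terminal placement of the best tier is
#' reported.
#'
#' @param protein Protein sequence.
#' @param window Number of C-terminal residues searched (default 10).
#' @param id Protein identifier.
#' @return One-row `data.frame` (`protein_id`, `start`, `match`, `tier`,
#'   `tier_rank`), or `NULL` when there is no match or the sequence is
#'   shorter than 4 residues.
#' @export
scan_sg7_terminal <- function(protein, window = 10, id = "protein") {
  if (window < 4) stop("`window` must be >= 4", call. = FALSE)
  chars <- seq_chars(protein)
  n <- length(chars)
  if (n < 4L) return(NULL)
  region_start <- max(1L, n - as.integer(window) + 1L)
  best <- NULL
  for (s in region_start:(n - 3L)) {
    if (chars[s + 2L] != "L" || chars[s + 3L] != "S") next
    rank <- (chars[s] == "W") + (chars[s + 1L] == "L")
    tier <- c("base", "W", "WL")[rank + 1L]
    if (rank == 1L && chars[s + 1L] == "L") tier <- "L"
    cand <- data.frame(
      protein_id = id, start = s,
      match = paste(chars[s:(s + 3L)], collapse = ""),
      tier = tier, tier_rank = as.integer(rank), stringsAsFactors = FALSE
    )
    if (is.null(best) || rank >= best$tier_rank) best <- cand
  }
  best
}

## Residue at canonical position 89 separates anthocyanin-type (A) from
## proanthocyanidin-type (G) regulators; isoleucine marks the atypical
## betalain-candidate clade.
INTERPRETATION_89 <- c(
  A = "anthocyanin-type", G = "proanthocyanidin-type", I = "C21-type"
)

#' Diagnostic residues of a canonically numbered R2R3 domain
#'
#' Reads the residues at canonical positions 44 (DNA-contact residue of the
#' R2 third helix), 60 and 98 (substitutable tryptophan landmarks) and 89
#' (regulator-type discriminator), interprets position 89, and flags an
#' atypical residue at 98: tryptophan is canonical and phenylalanine is a
#' rare but literature-known replacement, so anything else (including the
#' scannable cysteine substitution) raises the anomaly flag. Unmapped
#' positions (truncated domains) are reported as `"unknown"`.
#'
#' @param domain Output of [extract_domain()], or a plain 104-residue domain
#'   string.
#' @return `data.frame` with one row: `protein_id`, `res44`, `res60`,
#'   `res89`, `res98`, `interpretation_89`, `anomaly_98`.
#' @export
residue_diagnostics <- function(domain) {
  if (is.character(domain)) {
    domain <- list(domain = domain, protein_id = "protein",
                   map = data.frame(canonical = seq_len(nchar(domain))))
  }
  chars <- seq_chars(domain$domain)
  get_res <- function(p) {
    i <- match(p, domain$map$canonical)
    if (is.na(i) || i > length(chars)) "unknown" else chars[i]
  }
  r44 <- get_res(44); r60 <- get_res(60); r89 <- get_res(89); r98 <- get_res(98)
  interp <- if (r89 %in% names(INTERPRETATION_89)) {
    INTERPRETATION_89[[r89]]
  } else if (r89 == "unknown") "unknown" else "other"
  data.frame(
    protein_id = domain$protein_id,
    res44 = r44, res60 = r60, res89 = r89, res98 = r98,
    interpretation_89 = interp,
    anomaly_98 = !(r98 %in% c("W", "F")) && r98 != "unknown",
    stringsAsFactors = FALSE
  )
}

#' Read motif definitions from a text config
#'
#' One motif per line: `name<TAB>pattern<TAB>region<TAB>max_mismatch`
#' (`region` is `whole` or `cterm`); `#` starts a comment.
#'
#' @param path Config file path.
#' @return Named list of `motif_pattern` objects.
#' @export
read_motif_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 2L) stop("bad motif config line: ", ln, call. = FALSE)
    out[[f[1]]] <- motif_pattern(
      f[1], f[2],
      region = if (length(f) >= 3L) f[3] else "whole",
      max_mismatch = if (length(f) >= 4L) as.integer(f[4]) else 0L
    )
  }
  out
}
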