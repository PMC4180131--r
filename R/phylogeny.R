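## Landmark-anchored phylogenetic clade assignment: Poisson-corrected
## distances, neighbor joining with bootstrap support, and clade labelling of
## query proteins by the smallest supported landmark-pure group.

#' Pairwise distances over an alignment
#'
#' p-distance = mismatches / compared sites with pairwise deletion of
#' gap-containing columns; the Poisson correction is `d = -ln(1 - p)`, with
#' `p >= p_cap` mapped to `-ln(1 - p_cap)` because the correction diverges
#' as p approaches 1.
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (or `AAStringSet`); gaps are `-` or `.`.
#' @param model `"poisson"` (default) or `"p-distance"`.
#' @param p_cap Saturation cap on p before correction (default 0.95).
#' @return Symmetric `matrix` with zero diagonal, taxa as dimnames.
#' @export
pairwise_distance <- function(alignment, model = c("poisson", "p-distance"),
                              p_cap = 0.95) {
  model <- match.arg(model)
  seqs <- toupper(as.character(alignment))
  if (!is.null(names(alignment))) names(seqs) <- names(alignment)
  if (length(seqs) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment sequences must have equal length", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(seqs, seq_chars))
  is_res <- mat != "-" & mat != "."
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- is_res[i, ] & is_res[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        stop(sprintf("no comparable sites between %s and %s",
                     names(seqs)[i], names(seqs)[j]), call. = FALSE)
      }
      p <- sum(mat[i, comp] != mat[j, comp]) / nc
      dd <- if (model == "poisson") -log(1 - min(p, p_cap)) else p
      d[i, j] <- d[j, i] <- dd
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Classical NJ: at each step the pair minimising the Q criterion
#' `Q(i,j) = (r - 2) d(i,j) - R_i - R_j` is joined, with ties broken by the
#' lexicographically smallest taxon-label pair; branch lengths follow the
#' standard formulas and are clamped at zero. The final three lineages form
#' the unrooted trifurcation.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An [ape::read.tree()] `phylo` object (unrooted).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ## newick fragment per active node; `first` = lexicographically smallest
  ## leaf label under the node, used for deterministic tie-breaking
  frag <- labels
  first <- labels
  D <- dm
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- NULL
    qmin <- min(Q)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (Q[i, j] <= qmin + 1e-12) {
          key <- sort(c(first[i], first[j]))
          if (is.null(best) || key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])) {
            best <- list(i = i, j = j, key = key)
          }
        }
      }
    }
    i <- best$i; j <- best$j
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    new_first <- min(first[i], first[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    first <- c(first[keep], new_first)
    D <- D2
  }
  ## final trifurcation: closed-form branch lengths
  a <- D[1, 2]; b <- D[1, 3]; c_ <- D[2, 3]
  b1 <- max((a + b - c_) / 2, 0)
  b2 <- max((a + c_ - b) / 2, 0)
  b3 <- max((b + c_ - a) / 2, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], b1, frag[2], b2, frag[3], b3)
  ape::read.tree(text = nwk)
}

## Non-trivial bipartitions of an unrooted tree as canonical keys. The
## canonical side is the one containing the lexicographically smallest taxon
## label, so keys are comparable across trees over the same taxa regardless
## of tip order.
tree_splits <- function(tree) {
  tips <- tree$tip.label
  anchor <- min(tips)
  parts <- ape::prop.part(tree)
  out <- list()
  for (p in parts) {
    side <- tips[p]
    if (length(side) == length(tips)) next        # root: trivial
    if (length(side) < 2L) next                   # tip split
    if (length(side) > length(tips) - 2L) next    # complement of a tip
    if (!(anchor %in% side)) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    out[[key]] <- sort(side)
  }
  out
}

#' Bootstrap support for the internal edges of an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance-matrix NJ tree per replicate, and scores each internal edge of
#' the original tree by the percentage of replicates whose tree contains the
#' same bipartition. One seeded RNG stream drives all replicates, so results
#' do not depend on execution order; resampling is over column indices, so
#' supports are invariant to taxon input order.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param model,p_cap Passed to [pairwise_distance()].
#' @return List with `tree` (the original-tree `phylo`, with node labels set
#'   to integer percent supports; `NA` for the root) and `supports` (named
#'   numeric vector, bipartition key -> percent).
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1,
                              model = "poisson", p_cap = 0.95) {
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  seqs <- toupper(as.character(alignment))
  if (!is.null(names(alignment))) names(seqs) <- names(alignment)
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("alignment must be rectangular", call. = FALSE)
  mat <- do.call(rbind, lapply(seqs, seq_chars))
  rownames(mat) <- names(seqs)
  base_tree <- neighbor_joining(pairwise_distance(seqs, model, p_cap))
  base_splits <- tree_splits(base_tree)
  counts <- stats::setNames(rep(0L, length(base_splits)), names(base_splits))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rs <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      rep_tree <- tryCatch(
        neighbor_joining(pairwise_distance(rs, model, p_cap)),
        error = function(e) NULL
      )
      if (is.null(rep_tree)) next
      rep_keys <- names(tree_splits(rep_tree))
      hit <- names(counts) %in% rep_keys
      counts[hit] <- counts[hit] + 1L
    }
  })
  supports <- 100 * counts / n_reps
  list(tree = annotate_supports(base_tree, supports), supports = supports)
}

## Store supports as integer node labels on the phylo object. Nodes whose
## split is trivial (the root) keep an empty label.
annotate_supports <- function(tree, supports) {
  tips <- tree$tip.label
  anchor <- min(tips)
  parts <- ape::prop.part(tree)
  labs <- rep("", tree$Nnode)
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (length(side) == length(tips)) next
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    if (!(anchor %in% side)) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports)) labs[k] <- as.character(round(supports[key]))
  }
  tree$node.label <- labs
  tree
}

#' Assign query proteins to clades via landmark membership
#'
#' For each query, the smallest supported (>= `support_threshold`)
#' bipartition side containing the query together with at least one landmark
#' decides: if every landmark in it belongs to one clade, the query gets that
#' clade (with the edge's support); a mixed-clade side leaves the query
#' unassigned. A query whose smallest supported non-trivial side contains no
#' landmark at all, only other queries, is reported as a novel-clade
#' candidate (a species-specific group).
#'
#' @param tree A `phylo` whose node labels carry percent supports (from
#'   [bootstrap_support()]); trees without node labels are treated as fully
#'   supported.
#' @param landmark_map `data.frame` with `landmark_id`, `clade`, and
#'   optionally `subgroup`.
#' @param support_threshold Minimum percent support for a group to count
#'   (default 50).
#' @return `data.frame` with `query_id`, `clade` (`"unassigned"` or
#'   `"novel-candidate"` where applicable), `subgroup`, `landmarks`
#'   (semicolon-joined supporting landmarks or candidate partners),
#'   `support`.
#' @export
assign_clades <- function(tree, landmark_map, support_threshold = 50) {
  tips <- tree$tip.label
  missing <- setdiff(landmark_map$landmark_id, tips)
  if (length(missing)) {
    stop("landmarks missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  landmarks <- landmark_map$landmark_id
  queries <- setdiff(tips, landmarks)
  clade_of <- stats::setNames(landmark_map$clade, landmark_map$landmark_id)
  sub_of <- if (!is.null(landmark_map$subgroup)) {
    stats::setNames(landmark_map$subgroup, landmark_map$landmark_id)
  } else stats::setNames(rep(NA_character_, nrow(landmark_map)),
                         landmark_map$landmark_id)
  ## collect supported groups: each non-trivial split contributes both sides
  parts <- ape::prop.part(tree)
  labs <- tree$node.label
  groups <- list(); supps <- numeric(0)
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (length(side) == length(tips)) next
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    supp <- if (is.null(labs) || is.na(labs[k]) || labs[k] == "") 100
            else as.numeric(labs[k])
    if (is.na(supp) || supp < support_threshold) next
    comp <- setdiff(tips, side)
    groups <- c(groups, list(side), list(comp))
    supps <- c(supps, supp, supp)
  }
  rows <- lapply(queries, function(q) {
    containing <- which(vapply(groups, function(g) q %in% g, logical(1)))
    containing <- containing[order(lengths(groups)[containing])]
    for (gi in containing) {
      g <- groups[[gi]]
      lm <- intersect(g, landmarks)
      if (length(lm)) {
        cls <- unique(clade_of[lm])
        if (length(cls) == 1L) {
          return(data.frame(
            query_id = q, clade = cls,
            subgroup = unique(sub_of[lm])[1],
            landmarks = paste(sort(lm), collapse = ";"),
            support = supps[gi], stringsAsFactors = FALSE
          ))
        }
        return(data.frame(
          query_id = q, clade = "unassigned", subgroup = NA_character_,
          landmarks = paste(sort(lm), collapse = ";"),
          support = supps[gi], stringsAsFactors = FALSE
        ))
      }
      ## landmark-free supported group: species-specific cluster
      partners <- setdiff(g, q)
      if (length(partners) && all(partners %in% queries)) {
        return(data.frame(
          query_id = q, clade = "novel-candidate", subgroup = NA_character_,
          landmarks = paste(sort(partners), collapse = ";"),
          support = supps[gi], stringsAsFactors = FALSE
        ))
      }
    }
    data.frame(query_id = q, clade = "unassigned", subgroup = NA_character_,
               landmarks = "", support = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a support-annotated tree as Newick
#'
#' @param tree `phylo` with node labels (supports).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
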