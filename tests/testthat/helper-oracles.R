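## Independent oracles used to cross-check the implementation. These are
## deliberately naive re-implementations (plain loops, no shared helpers
## beyond the packaged constants) so agreement is meaningful.

## Random protein from the background residue distribution.
random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(names(aa_background()), n, replace = TRUE,
               prob = aa_background()), collapse = "")
}

## Exhaustive window scan: score every offset by direct summation, apply
## threshold + landmark rules, then greedy resolution (descending score,
## leftmost start on ties).
brute_scan <- function(protein, profile, id = "protein") {
  chars <- strsplit(toupper(protein), "")[[1]]
  plen <- profile$length
  n_win <- length(chars) - plen + 1
  cand <- list()
  if (n_win >= 1) {
    for (s in seq_len(n_win)) {
      sc <- 0
      for (k in seq_len(plen)) {
        res <- chars[s + k - 1]
        v <- if (res %in% colnames(profile$scores)) {
          profile$scores[k, res]
        } else 0
        sc <- sc + v
      }
      if (sc < profile$threshold) next
      ok <- TRUE
      for (p in names(profile$landmark_rules)) {
        if (!(chars[s + as.integer(p) - 1] %in% profile$landmark_rules[[p]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) cand[[length(cand) + 1]] <- c(start = s, score = unname(sc))
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "score"], cand[, "start"]), , drop = FALSE]
  taken <- rep(FALSE, length(chars))
  keep <- c()
  for (i in seq_len(nrow(cand))) {
    s <- cand[i, "start"]; e <- s + plen - 1
    if (!any(taken[s:e])) {
      taken[s:e] <- TRUE
      keep <- c(keep, i)
    }
  }
  out <- data.frame(start = as.integer(cand[keep, "start"]),
                    end = as.integer(cand[keep, "start"]) + plen - 1L,
                    score = as.numeric(cand[keep, "score"]))
  out[order(out$start), , drop = FALSE]
}

## Maximum window score over all offsets, by direct summation.
brute_scan_max <- function(protein, profile) {
  chars <- strsplit(toupper(protein), "")[[1]]
  n_win <- length(chars) - profile$length + 1
  if (n_win < 1) return(-Inf)
  max(vapply(seq_len(n_win), function(s) {
    direct_window_score(protein, s, profile)
  }, numeric(1)))
}

## Direct window score (no threshold logic) for a single offset.
direct_window_score <- function(protein, start, profile) {
  chars <- strsplit(toupper(protein), "")[[1]]
  sc <- 0
  for (k in seq_len(profile$length)) {
    res <- chars[start + k - 1]
    if (res %in% colnames(profile$scores)) sc <- sc + profile$scores[k, res]
  }
  unname(sc)
}

## Hand-executed median-of-ratios estimator (independent of DESeq2).
oracle_size_factors <- function(cm) {
  all_pos <- apply(cm, 1, function(r) all(r > 0))
  ref <- exp(rowMeans(log(cm[all_pos, , drop = FALSE])))
  vapply(seq_len(ncol(cm)), function(s) {
    stats::median(cm[all_pos, s] / ref)
  }, numeric(1))
}

## Naive O(n^3) centroid-linkage clustering on a row matrix. Returns the
## merge sequence: per step the sorted member set of the new cluster and the
## squared-Euclidean centroid distance at which it formed.
oracle_centroid_linkage <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), function(i) i)
  centroids <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  steps <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- sum((centroids[[i]] - centroids[[j]])^2)
        if (is.null(best) || d < best$d - 1e-12) best <- list(i = i, j = j, d = d)
      }
    }
    members <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    steps[[length(steps) + 1]] <- list(members = members, height = best$d)
    new_centroid <- colMeans(m[members, , drop = FALSE])
    keep <- setdiff(seq_along(clusters), c(best$i, best$j))
    clusters <- c(clusters[keep], list(members))
    centroids <- c(centroids[keep], list(new_centroid))
  }
  steps
}

## Member sets produced by an hclust merge matrix, in merge order.
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (s in seq_len(nrow(hc$merge))) {
    take <- function(v) {
      if (v < 0) -v else sets[[v]]
    }
    sets[[s]] <- sort(c(take(hc$merge[s, 1]), take(hc$merge[s, 2])))
  }
  sets
}

## All three unrooted 4-taxon topologies as trees with unit branch lengths.
four_taxon_topologies <- function(labels) {
  stopifnot(length(labels) == 4)
  lapply(list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3)), function(p) {
    ape::unroot(ape::read.tree(
      text = sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1);",
                     labels[p[1]], labels[p[2]],
                     labels[p[3]], labels[p[4]])
    ))
  })
}

## Mutate k positions of a sequence to a fixed residue (test scaffolding).
mutate_positions <- function(s, pos, to) {
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- to
  paste(ch, collapse = "")
}
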