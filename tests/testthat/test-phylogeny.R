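test_that("pairwise distances follow the Poisson correction", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "CCCCCAAAAA")
  d <- pairwise_distance(aln, model = "p-distance")
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.5)
  dp <- pairwise_distance(aln, model = "poisson")
  expect_equal(dp["a", "c"], log(2), tolerance = 1e-12)
  # symmetry and zero diagonal
  expect_true(isSymmetric(dp))
  expect_true(all(diag(dp) == 0))
  # saturation cap
  sat <- c(a = "AAAAAAAAAA", b = "CCCCCCCCCC", c = "AAAAACCCCC")
  ds <- pairwise_distance(sat, model = "poisson", p_cap = 0.95)
  expect_equal(ds["a", "b"], -log(0.05))
})

test_that("pairwise deletion skips gap columns and detects empty overlap", {
  aln <- c(a = "AA--AAAA", b = "AAAA--AA", c = "CCCCCCCC")
  d <- pairwise_distance(aln, model = "p-distance")
  expect_equal(d["a", "b"], 0)  # 4 comparable columns, all identical
  bad <- c(a = "AA----", b = "--AA--", c = "AAAA--")
  expect_error(pairwise_distance(bad), "no comparable sites.*a.*b")
})

test_that("distances equal an independent per-pair recount", {
  set.seed(33)
  taxa <- paste0("t", 1:10)
  aln <- vapply(taxa, function(t) random_protein(40, 5000 + match(t, taxa)),
                character(1))
  d <- pairwise_distance(aln, model = "p-distance")
  for (i in 1:9) for (j in (i + 1):10) {
    ci <- strsplit(aln[i], "")[[1]]
    cj <- strsplit(aln[j], "")[[1]]
    expect_equal(d[i, j], mean(ci != cj))
  }
})

test_that("NJ matches closed-form branch lengths on three taxa", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(dm)
  bl <- stats::setNames(tree$edge.length,
                        tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  asym <- dm; asym[1, 2] <- 10
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("NJ recovers generating topologies from additive matrices", {
  # 4 taxa: the recovered topology is the one whose additivity holds,
  # checked against enumeration of all three unrooted topologies
  tr <- ape::read.tree(text = "((A:1,B:2):1.5,(C:1,D:3):0.5);")
  dm <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(dm)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0,
               ignore_attr = TRUE)
  matches <- vapply(four_taxon_topologies(c("A", "B", "C", "D")),
                    function(t) ape::dist.topo(t, nj) == 0, logical(1))
  expect_equal(sum(matches), 1L)

  # additive 6- and 8-taxon matrices: the output path-length matrix equals
  # the input exactly
  for (n in c(6, 8)) {
    set.seed(n)
    gt <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    gt <- ape::unroot(gt)
    dm2 <- ape::cophenetic.phylo(gt)
    nj2 <- neighbor_joining(dm2)
    expect_equal(ape::dist.topo(gt, nj2), 0, ignore_attr = TRUE)
    path <- ape::cophenetic.phylo(nj2)[rownames(dm2), colnames(dm2)]
    expect_equal(path, dm2, tolerance = 1e-8)
  }
})

test_that("NJ agrees with an independent implementation on random matrices", {
  for (s in 1:5) {
    set.seed(600 + s)
    n <- 7
    m <- matrix(runif(n * n, 0.1, 2), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(paste0("x", 1:n), paste0("x", 1:n))
    ours <- neighbor_joining(m)
    ref <- ape::nj(m)
    expect_equal(ape::dist.topo(ape::unroot(ref), ours), 0,
                 ignore_attr = TRUE, info = s)
  }
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  set.seed(2)
  base <- random_protein(60, 71)
  aln <- c(
    a1 = base, a2 = mutate_positions(base, 1:3, "G"),
    a3 = mutate_positions(base, 4:6, "G"),
    b1 = mutate_positions(base, 10:40, "W"),
    b2 = mutate_positions(base, c(10:40, 50), "W")
  )
  bs <- bootstrap_support(aln, n_reps = 20, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(bs$tree, tmp)
  back <- ape::read.tree(tmp)
  expect_equal(ape::dist.topo(bs$tree, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(bs$tree$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label[nzchar(back$node.label)],
                  bs$tree$node.label[nzchar(bs$tree$node.label)])
})

test_that("bootstrap gives full support to clean splits and is deterministic", {
  set.seed(40)
  c1 <- random_protein(60, 81)
  c2 <- paste(rev(strsplit(random_protein(60, 82), "")[[1]]), collapse = "")
  aln <- c(a1 = c1, a2 = c1, a3 = c1, b1 = c2, b2 = c2, b3 = c2)
  bs <- bootstrap_support(aln, n_reps = 50, seed = 11)
  central <- bs$supports[["a1|a2|a3"]]
  expect_equal(central, 100)

  # n_reps = 1: supports are 0 or 100
  bs1 <- bootstrap_support(aln, n_reps = 1, seed = 12)
  expect_true(all(bs1$supports %in% c(0, 100)))

  # same seed twice: identical
  bs2 <- bootstrap_support(aln, n_reps = 50, seed = 11)
  expect_identical(bs$supports, bs2$supports)

  # taxon input order does not change canonical-split supports
  perm <- aln[c(4, 1, 5, 2, 6, 3)]
  bs3 <- bootstrap_support(perm, n_reps = 50, seed = 11)
  shared <- intersect(names(bs$supports), names(bs3$supports))
  expect_true(length(shared) >= 1)
  expect_equal(bs$supports[shared], bs3$supports[shared])
})

test_that("clade assignment follows landmark membership", {
  set.seed(50)
  c1 <- random_protein(80, 91)
  c2 <- paste(rev(strsplit(random_protein(80, 92), "")[[1]]), collapse = "")
  mut <- function(s, pos) mutate_positions(s, pos, "G")
  aln <- c(
    L1 = c1, L2 = mut(c1, 1:4), Q1 = mut(c1, 5:7),
    L3 = c2, L4 = mut(c2, 1:4),
    N1 = mut(c2, 20:60), N2 = mut(c2, c(20:60, 70))
  )
  bs <- bootstrap_support(aln, n_reps = 100, seed = 14)
  lm <- data.frame(
    landmark_id = c("L1", "L2", "L3", "L4"),
    clade = c("C1", "C1", "C2", "C2"),
    subgroup = c("S1", "S1", NA, NA)
  )
  asn <- assign_clades(bs$tree, lm)
  q1 <- asn[asn$query_id == "Q1", ]
  expect_equal(q1$clade, "C1")
  expect_true(q1$support >= 50)
  # the landmark-free pair is reported as a novel-clade candidate
  n1 <- asn[asn$query_id == "N1", ]
  expect_equal(n1$clade, "novel-candidate")
  expect_equal(n1$landmarks, "N2")

  expect_error(
    assign_clades(bs$tree, data.frame(landmark_id = "ZZ", clade = "C9")),
    "missing"
  )
})

test_that("queries without a supported or pure grouping stay unassigned", {
  lm <- data.frame(landmark_id = c("L1", "L2", "L3", "L4"),
                   clade = c("C1", "C1", "C2", "C2"))
  # symmetric placement with both internal edges below the support
  # threshold: no supported group contains Q
  weak <- ape::read.tree(
    text = "((L1:1,L2:1)30:1,(L3:1,L4:1)30:1,Q:1);"
  )
  asn <- assign_clades(weak, lm)
  expect_equal(asn$clade[asn$query_id == "Q"], "unassigned")
  expect_true(is.na(asn$support[asn$query_id == "Q"]))

  # fully supported but clade-mixed smallest group: also unassigned
  mixed <- ape::read.tree(
    text = "(((L1:1,L3:1)100:1,Q:1)100:1,(L2:1,L4:1)100:1);"
  )
  asn2 <- assign_clades(mixed, lm)
  expect_equal(asn2$clade[asn2$query_id == "Q"], "unassigned")
})
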