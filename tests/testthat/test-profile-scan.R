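profiles <- default_myb_profiles()
R2 <- myb_consensus("R2")
R3 <- myb_consensus("R3")

test_that("profile construction reflects seed columns and rejects bad input", {
  # identical seeds: consensus equals the sequence, with the maximal score
  # at every position
  prof <- build_profile(rep(R2, 5), kind = "R2")
  expect_equal(prof$consensus, R2)
  ch <- strsplit(R2, "")[[1]]
  for (k in seq_len(prof$length)) {
    expect_equal(names(which.max(prof$scores[k, ])), ch[k])
  }
  # background-expected score is <= 0 at every position
  bg <- aa_background()
  exp_score <- as.numeric(prof$scores %*% bg)
  expect_true(all(exp_score <= 1e-12))

  # two sequences differing at one position: both residues have equal counts
  # before pseudocounts (recovered by inverting the log-odds formula)
  v <- mutate_positions(R2, 10, "Q")  # position 10 E -> Q
  prof2 <- build_profile(c(R2, v), kind = "R2")
  bg <- aa_background()
  count_of <- function(res) {
    unname(exp(prof2$scores[10, res] + log(bg[[res]])) * (2 + 1) -
             1 * bg[[res]])
  }
  expect_equal(count_of("E"), 1, tolerance = 1e-9)
  expect_equal(count_of("Q"), 1, tolerance = 1e-9)

  expect_error(build_profile(c(R2, substr(R2, 1, 40))), "ragged")
  expect_error(build_profile(R2), "at least 2")
})

test_that("invariant positions carry maximal information in the seed profile", {
  seed_path <- system.file("extdata", "seed_r2_synthetic.afa",
                           package = "mybfam")
  seed <- as.character(Biostrings::readAAStringSet(seed_path))
  fm <- position_frequencies(align_repeats(seed, "R2"))
  # position 11 (invariant D) reaches the maximum information content
  expect_equal(fm$freq[11, "D"], 1)
  expect_equal(fm$information[11], max(fm$information))
})

test_that("scanner finds planted repeats and nothing in background decoys", {
  flank1 <- random_protein(40, seed = 301)
  flank2 <- random_protein(35, seed = 302)
  prot <- paste0(flank1, R2, R3, flank2)
  hits <- scan_myb_repeats(prot, profiles)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(41L, 94L))
  expect_equal(hits$repeat_kind, c("R2", "R3"))

  # no hits at the default threshold on background decoys
  for (s in 1:25) {
    decoy <- random_protein(300, seed = 400 + s)
    expect_identical(nrow(scan_protein(decoy, profiles$R2)), 0L)
    expect_identical(nrow(scan_protein(decoy, profiles$R3)), 0L)
  }

  # shorter than the profile: empty result, not an error
  expect_identical(nrow(scan_protein("ACDEF", profiles$R2)), 0L)
})

test_that("allowed landmark substitutions are detected and recorded", {
  # W98-equivalent (local 45 of the R3 window) replaced by cysteine
  r3_c98 <- mutate_positions(R3, 45, "C")
  prot <- paste0(random_protein(30, 77), R2, r3_c98, random_protein(30, 78))
  hits <- scan_myb_repeats(prot, profiles)
  expect_equal(nrow(hits), 2L)
  r3_hit <- hits[hits$repeat_kind == "R3", ]
  expect_match(r3_hit$landmark_evidence, "45=C\\*")
  # W60-equivalent substitutions from the allowed set also pass
  for (res in c("F", "I", "L", "Y")) {
    p2 <- paste0(random_protein(30, 79), mutate_positions(R3, 7, res))
    h2 <- scan_protein(p2, profiles$R3)
    expect_equal(nrow(h2), 1L)
    expect_match(h2$landmark_evidence, paste0("7=", res, "\\*"))
  }
  # a disallowed residue at a strict landmark kills the hit
  bad <- mutate_positions(R2, 26, "A")
  expect_identical(nrow(scan_protein(paste0("AAAA", bad), profiles$R2)), 0L)
})

test_that("scan equals the exhaustive window-scoring oracle", {
  gen <- generate_proteome(n_r2r3 = 8, n_decoy = 8, sub_rate = 0.1,
                           seed = 55)
  for (id in names(gen$proteome)) {
    prot <- gen$proteome[[id]]
    for (kind in c("R2", "R3")) {
      got <- scan_protein(prot, profiles[[kind]], id = id)
      want <- brute_scan(prot, profiles[[kind]], id = id)
      expect_equal(got$start, want$start, info = paste(id, kind))
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("raising the threshold never adds hits", {
  gen <- generate_proteome(n_r2r3 = 5, n_decoy = 5, sub_rate = 0.2, seed = 9)
  for (id in names(gen$proteome)) {
    prof_lo <- profiles$R2
    prof_hi <- profiles$R2
    prof_hi$threshold <- prof_lo$threshold + 25
    lo <- scan_protein(gen$proteome[[id]], prof_lo)
    hi <- scan_protein(gen$proteome[[id]], prof_hi)
    expect_true(nrow(hi) <= nrow(lo))
    expect_true(all(hi$start %in% lo$start))
  }
})

test_that("repeat kind is decided by profile score with a tie band", {
  prot <- paste0(R2, R3)
  expect_equal(classify_repeat_kind(prot, 1, profiles$R2, profiles$R3), "R2")
  expect_equal(classify_repeat_kind(prot, 54, profiles$R2, profiles$R3), "R3")

  # chimeric window: alternate residues of the two consensi, then verify the
  # margin by direct summation and pick tolerances around it
  ch2 <- strsplit(R2, "")[[1]]
  ch3 <- strsplit(R3, "")[[1]]
  chim <- ch2[1:51]
  chim[seq(2, 51, by = 2)] <- ch3[seq(2, 51, by = 2)]
  chim <- paste(c(chim, ch2[52:53]), collapse = "")
  s2 <- direct_window_score(chim, 1, profiles$R2) / profiles$R2$length
  s3 <- direct_window_score(chim, 1, profiles$R3) / profiles$R3$length
  margin <- abs(s2 - s3)
  expect_equal(
    classify_repeat_kind(chim, 1, profiles$R2, profiles$R3,
                         tie_tol = margin + 0.01),
    "unclassified"
  )
  expect_true(
    classify_repeat_kind(chim, 1, profiles$R2, profiles$R3,
                         tie_tol = margin / 2) %in% c("R2", "R3")
  )
})

test_that("family class follows repeat count with a CDC5 override", {
  hit_rows <- function(n) {
    data.frame(
      protein_id = rep("p", n), start = seq(1, by = 60, length.out = n),
      end = seq(53, by = 60, length.out = n), score = rep(100, n),
      repeat_kind = rep(c("R2", "R3"), length.out = n),
      landmark_evidence = rep("", n), stringsAsFactors = FALSE
    )
  }
  classes <- vapply(0:4, function(n) {
    classify_protein(hit_rows(n))$family_class
  }, character(1))
  expect_equal(classes, c("non-MYB", "single-repeat", "R2R3", "MYB3R",
                          "MYB4R"))
  # pure function: same hits give the same class
  expect_identical(classify_protein(hit_rows(2))$family_class,
                   classify_protein(hit_rows(2))$family_class)

  # CDC5 override: a mutated copy of the landmark is still > 40% identical
  cdc5 <- as.character(Biostrings::readAAStringSet(system.file(
    "extdata", "cdc5_landmark_synthetic.fasta", package = "mybfam"
  )))[[1]]
  set.seed(31)
  noisy <- strsplit(cdc5, "")[[1]]
  idx <- sample(length(noisy), 40)
  noisy[idx] <- "A"
  noisy <- paste(noisy, collapse = "")
  cls <- classify_protein(hit_rows(2), noisy, "q", cdc5_landmark = cdc5)
  expect_equal(cls$family_class, "CDC5-like")
  # an ordinary synthetic R2R3 protein is not captured by the override
  gen <- generate_proteome(n_r2r3 = 1, sub_rate = 0, seed = 12)
  id <- names(gen$proteome)[1]
  hits <- scan_myb_repeats(gen$proteome[[id]], profiles, id = id)
  cls2 <- classify_protein(hits, gen$proteome[[id]], id,
                           cdc5_landmark = cdc5)
  expect_equal(cls2$family_class, "R2R3")
})

test_that("domain extraction maps canonical positions onto the protein", {
  off <- 28L
  prot <- paste0(random_protein(off - 1L, 501), R2, R3,
                 random_protein(20, 502))
  hits <- scan_myb_repeats(prot, profiles, id = "p")
  cls <- classify_protein(hits, prot, "p")
  dom <- extract_domain(cls, prot)
  expect_equal(nchar(dom$domain), 104L)
  expect_equal(substr(dom$domain, 11, 11), "D")
  expect_equal(substr(dom$domain, 43, 43), "C")
  expect_equal(substr(dom$domain, 46, 46), "R")
  expect_equal(substr(dom$domain, 98, 98), "W")
  expect_equal(dom$map$protein[dom$map$canonical == 1], off)
  expect_equal(dom$map$protein[dom$map$canonical == 54], off + 53L)

  bad <- classify_protein(hits[1, , drop = FALSE])
  expect_error(extract_domain(bad, prot), "R2R3")
})
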