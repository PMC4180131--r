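profiles <- default_myb_profiles()

test_that("zero-noise plants are exact consensus copies at the truth intervals", {
  gen <- generate_proteome(n_r2r3 = 1, sub_rate = 0, seed = 1)
  expect_length(gen$proteome, 1L)
  tr <- gen$truth$protein_truth[[1]]
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$repeat_kind, c("R2", "R3"))
  prot <- gen$proteome[[1]]
  expect_equal(substr(prot, tr$start[1], tr$end[1]), myb_consensus("R2"))
  expect_equal(substr(prot, tr$start[2], tr$end[2]), myb_consensus("R3"))
  # intervals lie within the protein
  expect_true(all(tr$start >= 1 & tr$end <= nchar(prot)))
  expect_equal(tr$substitutions, c("", ""))
})

test_that("decoys carry no truth repeats and draw from the background", {
  gen <- generate_proteome(n_decoy = 5, sub_rate = 0.3, seed = 2)
  expect_length(gen$proteome, 5L)
  for (tr in gen$truth$protein_truth) expect_equal(nrow(tr), 0L)
})

test_that("generator arguments are validated", {
  expect_error(generate_proteome(n_r2r3 = -1, seed = 1), ">= 0")
  expect_error(generate_proteome(n_r2r3 = 1, sub_rate = 0.5, seed = 1),
               "sub_rate")
  expect_error(generate_counts(10, c("a", "b"), c(1, -1), seed = 1),
               "positive")
  expect_error(generate_counts(10, c("a", "b"), 1, seed = 1), "one scale")
})

test_that("generation is deterministic given the seed", {
  a <- generate_proteome(n_r2r3 = 4, n_decoy = 4, sub_rate = 0.1, seed = 77)
  b <- generate_proteome(n_r2r3 = 4, n_decoy = 4, sub_rate = 0.1, seed = 77)
  expect_identical(a, b)
  c <- generate_proteome(n_r2r3 = 4, n_decoy = 4, sub_rate = 0.1, seed = 78)
  expect_false(identical(a$proteome, c$proteome))

  layout <- random_gene_layout(10, seed = 5)
  layout2 <- random_gene_layout(10, seed = 5)
  expect_identical(layout, layout2)
  g1 <- generate_gene_models(layout)
  g2 <- generate_gene_models(layout2)
  expect_identical(g1$gff3, g2$gff3)  # byte-identical text

  m1 <- generate_counts(50, c("a", "b", "c"), c(1, 2, 3), seed = 10)
  m2 <- generate_counts(50, c("a", "b", "c"), c(1, 2, 3), seed = 10)
  expect_identical(m1$counts, m2$counts)
})

test_that("substitutions respect landmark rules", {
  gen <- generate_proteome(n_r2r3 = 30, sub_rate = 0.3, seed = 21)
  for (id in names(gen$proteome)) {
    tr <- gen$truth$protein_truth[[id]]
    prot <- strsplit(gen$proteome[[id]], "")[[1]]
    for (k in seq_len(nrow(tr))) {
      win <- prot[tr$start[k]:tr$end[k]]
      rules <- if (tr$repeat_kind[k] == "R2") {
        list(`7` = "W", `26` = "W", `45` = "W")
      } else {
        list(`7` = c("W", "F", "I", "L", "Y"), `26` = "W",
             `45` = c("W", "F", "C"))
      }
      for (p in names(rules)) {
        expect_true(win[as.integer(p)] %in% rules[[p]],
                    info = paste(id, k, p))
      }
    }
  }
})

test_that("planted repeats outscore every decoy window in the zero-noise case", {
  gen <- generate_proteome(n_r2r3 = 3, n_decoy = 30, sub_rate = 0, seed = 13)
  decoy_ids <- grep("decoy", names(gen$proteome), value = TRUE)
  decoy_max <- max(vapply(decoy_ids, function(id) {
    prot <- gen$proteome[[id]]
    m2 <- brute_scan_max(prot, profiles$R2)
    m3 <- brute_scan_max(prot, profiles$R3)
    max(m2, m3)
  }, numeric(1)))
  for (id in setdiff(names(gen$proteome), decoy_ids)) {
    tr <- gen$truth$protein_truth[[id]]
    for (k in seq_len(nrow(tr))) {
      prof <- profiles[[tr$repeat_kind[k]]]
      sc <- direct_window_score(gen$proteome[[id]], tr$start[k], prof)
      expect_gt(sc, decoy_max)
    }
  }
})

test_that("gene-model generation lays out exons and tandem pairs as asked", {
  # two genes at the observed tandem spacing are recorded as a pair
  layout <- data.frame(
    gene_id = c("ahzs", "eztu"), chromosome = c("chr7", "chr7"),
    start = c(37491045L, 37594009L), exon_n = c(3L, 3L)
  )
  gm <- generate_gene_models(layout)
  expect_equal(gm$truth$gene_truth$tandem_partner, c("eztu", "ahzs"))

  # single gene with 3 exons -> exactly 3 exon features
  one <- generate_gene_models(data.frame(
    gene_id = "g1", chromosome = "chr1", start = 1000L, exon_n = 3L
  ))
  expect_equal(sum(grepl("\tgene\t", one$gff3)), 1L)
  expect_equal(sum(grepl("\texon\t", one$gff3)), 3L)
  expect_equal(one$gff3[1], "##gff-version 3")

  # overlapping bodies are rejected
  expect_error(generate_gene_models(data.frame(
    gene_id = c("a", "b"), chromosome = "chr1",
    start = c(1000L, 1100L), exon_n = c(3L, 3L)
  )), "overlap")
})

test_that("count generation respects scale factors and presence patterns", {
  # null case: all factors 1 -> estimates near 1
  gen <- generate_counts(400, c("a", "b", "c"), c(1, 1, 1), seed = 6)
  sf <- size_factors(gen$counts)
  expect_true(all(abs(sf - 1) < 0.1))

  # factor ratio recovered within 5%
  gen2 <- generate_counts(500, c("a", "b"), c(1, 2), seed = 7)
  sf2 <- size_factors(gen2$counts)
  expect_lt(abs(sf2[["b"]] / sf2[["a"]] - 2) / 2, 0.05)

  # silenced genes are absent from every downstream presence call
  gen3 <- generate_counts(60, c("a", "b"), c(1, 1), seed = 8,
                          prop_silent = 0.2)
  silent <- rowSums(gen3$truth$expression_truth$presence_pattern) == 0
  expect_true(any(silent))
  pres <- presence_calls(normalize_counts(gen3$counts))
  expect_true(all(!pres$presence[silent, ]))
  expect_true(all(gen3$counts[silent, ] == 0))
})

test_that("generated artefacts round-trip through their file formats", {
  tmp <- withr::local_tempdir()
  gen <- generate_proteome(n_r2r3 = 2, n_decoy = 1, sub_rate = 0, seed = 3)
  fa <- file.path(tmp, "prot.fasta")
  write_proteome_fasta(gen$proteome, fa)
  back <- as.character(Biostrings::readAAStringSet(fa))
  expect_equal(unname(back), unname(unlist(gen$proteome)))
  expect_equal(names(back), names(gen$proteome))
  # 60-column wrap
  body <- readLines(fa)
  expect_true(all(nchar(body[!startsWith(body, ">")]) <= 60))

  layout <- random_gene_layout(6, seed = 2)
  gm <- generate_gene_models(layout)
  gff <- file.path(tmp, "genes.gff3")
  write_gff3(gm$gff3, gff)
  models <- read_gene_models(gff)
  expect_equal(sort(models$gene_id), sort(layout$gene_id))
  expect_equal(models$exon_n[match(layout$gene_id, models$gene_id)],
               as.integer(layout$exon_n))

  cnt <- generate_counts(20, c("x", "y"), c(1, 1), seed = 4)
  tsv <- file.path(tmp, "counts.tsv")
  write_counts_tsv(cnt$counts, tsv)
  back2 <- read_counts_tsv(tsv)
  expect_equal(back2, cnt$counts)

  js <- file.path(tmp, "truth.json")
  write_truth_json(gen$truth, js)
  expect_true(file.exists(js))
  expect_silent(jsonlite::read_json(js))
})
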