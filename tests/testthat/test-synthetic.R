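test_that("generation is deterministic and byte-identical for a fixed seed", {
  tx <- taxa_spec(c("PhyA", "PhyB"), n = 3,
                  defect = c("none", "terminal_mismatch"),
                  defect_frac = c(0, 0.5))
  ref1 <- simulate_reference_set(tx, seed = 301)
  ref2 <- simulate_reference_set(tx, seed = 301)
  expect_identical(ref1$records, ref2$records)
  ref3 <- simulate_reference_set(tx, seed = 302)
  expect_false(identical(ref1$records$sequence, ref3$records$sequence))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_reference_set(ref1, d1)
  p2 <- write_reference_set(ref2, d2)
  expect_identical(unname(tools::md5sum(p1[["fasta"]])),
                   unname(tools::md5sum(p2[["fasta"]])))
})

test_that("planted defects re-score at their closed-form values", {
  cfg <- scoring_config()
  p341 <- default_primers()[default_primers()$name == "341f", ]

  one_of <- function(defect, frac = 1) {
    tx <- taxa_spec("Phy", 1, defect, frac)
    simulate_reference_set(tx, seed = 11, config = cfg)
  }
  score_of <- function(ref) {
    hits <- score_primers(ref$records, p341, cfg)
    hits[1, ]
  }

  h_term <- score_of(one_of("terminal_mismatch"))
  expect_equal(h_term$weighted_score, 4.0)
  expect_true(h_term$last_base_mismatch)
  expect_identical(h_term$start, 341L)

  h_non3p <- score_of(one_of("non3p_mismatch"))
  expect_equal(h_non3p$weighted_score, 0.4)
  expect_false(h_non3p$last_base_mismatch)

  h_gap <- score_of(one_of("site_gap"))
  expect_equal(h_gap$weighted_score, 1.0)
  expect_identical(h_gap$non3p_gaps, 1L)
})

test_that("defect planting rejects impossible positions", {
  p341 <- default_primers()[default_primers()$name == "341f", ]
  tmpl <- paste(rep("A", 400), collapse = "")
  expect_error(plant_defect(tmpl, p341, 341, "mismatch", 99),
               "outside primer length")
  # position 9 of 341f is N: every base matches, no mismatch can be planted
  expect_error(plant_defect(tmpl, p341, 341, "mismatch", 9),
               "cannot plant mismatch against N")
})

test_that("pipeline recovers the truth manifest exactly across seeds and methods", {
  tx <- taxa_spec(c("PhyA", "PhyB", "PhyC"), n = 6,
                  defect = c("none", "terminal_mismatch", "double_mismatch"),
                  defect_frac = c(0, 0.5, 0.5))
  for (seed in 1:10) {
    ref <- simulate_reference_set(tx, seed = seed)
    hits <- score_primers(ref$records, ref$primers, scoring_config())
    for (method in c("weighted", "tp")) {
      cfg <- scoring_config(method = method)
      cov <- coverage_by_taxon(hits, ref$records, "phylum", cfg,
                               pair = c("341f", "785r"))
      truth <- ref$truth[ref$truth$method == method, ]
      m <- dplyr::inner_join(tibble::as_tibble(cov), truth, by = "taxon")
      expect_equal(m$coverage_pct, m$expected_coverage_pct,
                   info = paste("seed", seed, method))
    }
  }
})

test_that("stochastic planting records realised counts in the manifest", {
  tx <- taxa_spec("PhyA", 12, "terminal_mismatch", 0.5)
  ref <- simulate_reference_set(tx, seed = 404, stochastic = TRUE)
  k <- ref$n_defect
  expect_identical(sum(ref$records$defective), as.integer(k))
  truth_w <- ref$truth[ref$truth$method == "weighted", ]
  expect_equal(truth_w$expected_non_coverage_pct, 100 * k / 12)
  hits <- score_primers(ref$records, ref$primers, scoring_config())
  cov <- coverage_by_taxon(hits, ref$records, "phylum", scoring_config(),
                           pair = c("341f", "785r"))
  expect_equal(cov$non_coverage_pct, truth_w$expected_non_coverage_pct)
})

test_that("generated FASTA round-trips through the SILVA reader", {
  tx <- taxa_spec(c("PhyA", "PhyB"), n = 2)
  ref <- simulate_reference_set(tx, seed = 21)
  dir <- withr::local_tempdir()
  paths <- write_reference_set(ref, dir)
  back <- read_silva_fasta(paths[["fasta"]])
  expect_identical(back$id, ref$records$id)
  expect_identical(back$sequence, ref$records$sequence)
  expect_identical(back$taxonomy, ref$records$taxonomy)
  # taxonomy TSV agrees, and can override header taxonomy
  tax <- read_taxonomy_tsv(paths[["taxonomy"]])
  expect_identical(tax$taxonomy, ref$records$taxonomy)
  back2 <- read_silva_fasta(paths[["fasta"]], taxonomy = tax)
  expect_identical(back2$taxonomy, ref$records$taxonomy)
})
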