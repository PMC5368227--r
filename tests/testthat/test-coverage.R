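test_that("pair amplifiability needs both passing scores and ordered sites", {
  fx <- fixture_mixed()
  ph <- pair_hit_table(fx$hits, "341f", "785r")
  rid_good <- fx$ref$records$id[!fx$ref$records$defective][1]
  rid_bad <- fx$ref$records$id[fx$ref$records$defective &
                                grepl("PhyB", fx$ref$records$id)][1]
  f_good <- fx$hits[fx$hits$primer_name == "341f" & fx$hits$record_id == rid_good, ]
  r_good <- fx$hits[fx$hits$primer_name == "785r" & fx$hits$record_id == rid_good, ]
  f_bad <- fx$hits[fx$hits$primer_name == "341f" & fx$hits$record_id == rid_bad, ]
  r_bad <- fx$hits[fx$hits$primer_name == "785r" & fx$hits$record_id == rid_bad, ]

  expect_true(sequence_amplifiable(f_good, r_good, fx$cfg))
  # terminal 3' mismatch: forward score 4.0 > threshold 1.0
  expect_equal(f_bad$weighted_score, 4.0)
  expect_false(sequence_amplifiable(f_bad, r_bad, fx$cfg))
  # infinite threshold admits any finite, ordered site pair
  cfg_inf <- fx$cfg
  cfg_inf$hit_threshold <- Inf
  expect_true(sequence_amplifiable(f_bad, r_bad, cfg_inf))
  # hits from different records are a consistency error
  expect_error(sequence_amplifiable(f_good, r_bad, fx$cfg),
               "different records")
})

test_that("per-phylum coverage recovers the planted defect quotas exactly", {
  fx <- fixture_mixed()
  cov <- coverage_by_taxon(fx$hits, fx$ref$records, "phylum", fx$cfg,
                           pair = fx$pair)
  truth <- fx$ref$truth[fx$ref$truth$method == "weighted" &
                          fx$ref$truth$pair == "341f/785r", ]
  m <- dplyr::inner_join(tibble::as_tibble(cov), truth, by = "taxon")
  expect_identical(nrow(m), 4L)
  expect_equal(m$coverage_pct, m$expected_coverage_pct)
  expect_equal(m$non_coverage_pct, m$expected_non_coverage_pct)
  # PhyB: 2 of 10 terminal mismatches -> 80/20 split
  expect_equal(cov$coverage_pct[cov$taxon == "PhyB"], 80)
  expect_equal(cov$non_coverage_pct[cov$taxon == "PhyB"], 20)
  # conservation: totals sum to the records passing the denominator policy
  expect_identical(sum(cov$n_total), nrow(fx$ref$records))
  # rows sorted by descending n_total
  expect_true(!is.unsorted(rev(cov$n_total)))
})

test_that("domain coverage is the size-weighted mean of phylum coverages", {
  fx <- fixture_mixed()
  cov_p <- coverage_by_taxon(fx$hits, fx$ref$records, "phylum", fx$cfg,
                             pair = fx$pair)
  cov_d <- coverage_by_taxon(fx$hits, fx$ref$records, "domain", fx$cfg,
                             pair = fx$pair)
  expect_identical(nrow(cov_d), 1L)
  expect_equal(cov_d$coverage_pct,
               sum(cov_p$coverage_pct * cov_p$n_total) / sum(cov_p$n_total))
})

test_that("coverage is monotone non-decreasing in the hit threshold", {
  fx <- fixture_mixed()
  covs <- vapply(c(0, 0.5, 1, 2, 5), function(thr) {
    cfg <- fx$cfg
    cfg$hit_threshold <- thr
    cov <- coverage_by_taxon(fx$hits, fx$ref$records, "domain", cfg,
                             pair = fx$pair)
    cov$coverage_pct
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("terminal-base mismatch fractions match the planted rates", {
  fx <- fixture_mixed()
  lb <- last_base_mismatch_fraction(fx$hits, fx$ref$records, "phylum")
  lb341 <- lb[lb$primer_name == "341f", ]
  expect_equal(lb341$last_base_mm_pct[lb341$taxon == "PhyB"], 20)
  expect_equal(lb341$last_base_mm_pct[lb341$taxon == "PhyA"], 0)
  lb785 <- lb[lb$primer_name == "785r", ]
  expect_true(all(lb785$last_base_mm_pct == 0))

  # 1 planted terminal mismatch in 20 records -> 5.0%
  tx <- taxa_spec("PhyX", 20, "terminal_mismatch", 0.05)
  ref <- simulate_reference_set(tx, seed = 77)
  hits <- score_primers(ref$records, ref$primers, scoring_config())
  lb1 <- last_base_mismatch_fraction(hits, ref$records, "phylum")
  expect_equal(lb1$last_base_mm_pct[lb1$primer_name == "341f"], 5.0)
})

test_that("weighted and total-mismatch methods diverge as documented", {
  fx <- fixture_mixed()
  cmp <- compare_methods(fx$hits, fx$ref$records, "phylum", fx$cfg,
                         pair = fx$pair)
  # terminal-3'-only defects: weighted flags them, tp (score 1.0) passes
  expect_equal(cmp$non_coverage_weighted[cmp$taxon == "PhyB"], 20)
  expect_equal(cmp$non_coverage_tp[cmp$taxon == "PhyB"], 0)
  # all-perfect taxon: both methods at zero
  expect_equal(cmp$non_coverage_weighted[cmp$taxon == "PhyA"], 0)
  expect_equal(cmp$non_coverage_tp[cmp$taxon == "PhyA"], 0)
  # two mismatches per defective site: both methods flag every defective
  # record (weighted 1.4 > 1, tp 2.0 > 1)
  expect_equal(cmp$non_coverage_weighted[cmp$taxon == "PhyC"], 50)
  expect_equal(cmp$non_coverage_tp[cmp$taxon == "PhyC"], 50)
  # single non-3' mismatch (0.4): neither method flags it
  expect_equal(cmp$non_coverage_weighted[cmp$taxon == "PhyD"], 0)
  expect_equal(cmp$non_coverage_tp[cmp$taxon == "PhyD"], 0)
})

test_that("tp non-coverage cannot exceed weighted non-coverage when all weights >= 1", {
  cfg <- scoring_config(w_non3p_mm = 1.0)
  tx <- taxa_spec(c("PhyA", "PhyB", "PhyC"), n = 6,
                  defect = c("terminal_mismatch", "double_mismatch", "non3p_mismatch"),
                  defect_frac = c(0.5, 0.5, 0.5))
  ref <- simulate_reference_set(tx, seed = 99, config = cfg)
  hits <- score_primers(ref$records, ref$primers, cfg)
  cmp <- compare_methods(hits, ref$records, "phylum", cfg, pair = c("341f", "785r"))
  expect_true(all(cmp$non_coverage_tp <= cmp$non_coverage_weighted + 1e-9))
})

test_that("missing taxonomy buckets as Unclassified and deep ranks warn", {
  fx <- fixture_mixed()
  records <- fx$ref$records
  records$taxonomy[1] <- NA_character_
  cov <- coverage_by_taxon(fx$hits, records, "phylum", fx$cfg, pair = fx$pair)
  expect_true("Unclassified" %in% cov$taxon)
  expect_identical(sum(cov$n_total), nrow(records))

  shallow <- records
  shallow$taxonomy <- "Bacteria"
  expect_warning(
    empty <- coverage_by_taxon(fx$hits, shallow, "genus", fx$cfg, pair = fx$pair),
    "deeper")
  expect_identical(nrow(empty), 0L)
})
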