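test_that("weighted score applies the 3'-weighted coefficients and terminal penalty", {
  expect_equal(weighted_score(0, 0, 0, 0, FALSE), 0.0)
  expect_equal(weighted_score(1, 0, 0, 0, FALSE), 0.40)
  expect_equal(weighted_score(0, 1, 0, 0, TRUE), 4.00)
  expect_equal(weighted_score(2, 1, 0, 1, FALSE), 4.80)
  expect_equal(weighted_score(0, 0, 1, 0, FALSE), 1.00)
  expect_equal(weighted_score(0, 0, 0, 1, FALSE), 3.00)
  expect_error(weighted_score(-1, 0, 0, 0), "non-negative")
})

test_that("tp score is the unit-weight mismatch+gap count", {
  expect_equal(tp_score(0, 0), 0.0)
  expect_equal(tp_score(3, 0), 3.0)
  expect_equal(tp_score(2, 1), 3.0)
  expect_error(tp_score(-2), "non-negative")
})

test_that("a terminal 3' mismatch scores 4.0 weighted but only 1.0 total-mismatch", {
  # planted site with mutated final base in an alignment-hostile background
  # (primer 3' terminus differs from its neighbour, so no internal deletion
  # can re-pair the final base with an adjacent identical template base)
  primer <- "ACGGACCAGC"
  site <- "ACGGACCAGA"
  template <- paste0(strrep("T", 20), site, strrep("T", 20))
  hit <- align_primer(primer, template)
  expect_equal(hit$weighted_score, 4.0)
  expect_equal(hit$tp_score, 1.0)
  expect_true(hit$last_base_mismatch)
  expect_identical(hit$start, 21L)
  expect_identical(hit$end, 30L)
})

test_that("align_primer finds planted perfect sites with exact coordinates", {
  cfg <- scoring_config(three_prime_len = 2)
  hit <- align_primer("ACGT", "TTACGTTT", cfg)
  expect_equal(hit$weighted_score, 0.0)
  expect_identical(hit$start, 3L)
  expect_identical(hit$end, 6L)
  expect_false(hit$truncated)

  # fully degenerate primer matches any concrete window
  hit_n <- align_primer("NNNN", "GATTACAA", cfg)
  expect_equal(hit_n$weighted_score, 0.0)

  # template shorter than primer: flagged, never a hit
  short <- align_primer("ACGTACGT", "ACG", cfg)
  expect_true(short$truncated)
  expect_identical(short$weighted_score, Inf)
})

test_that("best score on a mismatched template equals exhaustive enumeration", {
  cfg <- scoring_config(three_prime_len = 2)
  hit <- align_primer("ACGT", "TTACGATT", cfg)
  expect_equal(hit$weighted_score, oracle_best_score("ACGT", "TTACGATT", cfg))
  # enumeration puts the best window at "GATT": two non-3' + one 3' mismatch
  expect_equal(hit$weighted_score, 1.8)
  expect_false(hit$last_base_mismatch)
})

test_that("search equals the brute-force oracle across configurations", {
  configs <- list(
    scoring_config(),
    scoring_config(max_gaps = 0L),
    scoring_config(max_gaps = 1L, three_prime_len = 3L),
    scoring_config(w_non3p_mm = 0.7, w_3p_gap = 2.5, terminal_penalty = 1.5)
  )
  withr::with_seed(202, {
    for (cfg in configs) {
      for (rep in 1:15) {
        L <- sample(4:12, 1)
        primer <- random_primer(L)
        template <- random_template(sample(L:60, 1))
        hit <- align_primer(primer, template, cfg)
        expect_equal(hit$weighted_score, oracle_best_score(primer, template, cfg),
                     info = paste(primer, template))
        # reported counts must reproduce the reported score
        expect_equal(
          hit$weighted_score,
          weighted_score(hit$non3p_mismatches, hit$threep_mismatches,
                         hit$non3p_gaps, hit$threep_gaps,
                         hit$last_base_mismatch, cfg))
      }
    }
  })
})

test_that("reverse-primer search is strand-symmetric with mapped coordinates", {
  withr::with_seed(303, {
    for (rep in 1:20) {
      L <- sample(5:12, 1)
      p_seq <- random_primer(L)
      template <- random_template(sample((L + 5):60, 1))
      fwd <- primer_set("p", p_seq, "forward")
      rev <- primer_set("p", p_seq, "reverse")
      h_rev <- align_primer(rev, template)
      h_fwd <- align_primer(fwd, reverse_complement(template))
      expect_equal(h_rev$weighted_score, h_fwd$weighted_score)
      expect_identical(h_rev$last_base_mismatch, h_fwd$last_base_mismatch)
      Tn <- nchar(template)
      expect_identical(h_rev$start, Tn - h_fwd$end + 1L)
      expect_identical(h_rev$end, Tn - h_fwd$start + 1L)
    }
  })
})

test_that("an extra mismatch in the best site never lowers the best score", {
  # primers avoid T entirely so a T substitution is a mismatch at EVERY
  # primer position and cannot improve any alternative alignment
  no_t_codes <- c("A", "C", "G", "M", "R", "S", "V")
  withr::with_seed(404, {
    checked <- 0
    for (rep in 1:40) {
      L <- sample(5:10, 1)
      primer <- paste(sample(no_t_codes, L, replace = TRUE,
                             prob = c(3, 3, 3, 1, 1, 1, 1)), collapse = "")
      template <- random_template(sample(L:50, 1), alphabet = c("A", "C", "G"))
      hit <- align_primer(primer, template)
      if (hit$non3p_gaps + hit$threep_gaps > 0) next  # need base-to-base map
      t_chars <- strsplit(template, "", fixed = TRUE)[[1]]
      p_chars <- strsplit(primer, "", fixed = TRUE)[[1]]
      matching <- which(vapply(seq_len(L), function(i) {
        iupac_match(p_chars[i], t_chars[hit$start + i - 1L])
      }, logical(1)))
      if (length(matching) == 0) next
      i <- sample(matching, 1)
      t_chars[hit$start + i - 1L] <- "T"
      hit2 <- align_primer(primer, paste(t_chars, collapse = ""))
      expect_gte(hit2$weighted_score, hit$weighted_score - 1e-9)
      checked <- checked + 1
    }
    expect_gte(checked, 10)
  })
})

test_that("score zero exactly when some window matches the primer gap-free", {
  withr::with_seed(505, {
    for (rep in 1:20) {
      L <- sample(5:10, 1)
      primer <- random_primer(L)
      template <- random_template(sample(L:40, 1))
      hit <- align_primer(primer, template)
      p_chars <- strsplit(primer, "", fixed = TRUE)[[1]]
      t_chars <- strsplit(template, "", fixed = TRUE)[[1]]
      perfect_window <- any(vapply(1:(nchar(template) - L + 1), function(s) {
        all(vapply(seq_len(L), function(i) {
          iupac_match(p_chars[i], t_chars[s + i - 1L])
        }, logical(1)))
      }, logical(1)))
      expect_identical(hit$weighted_score == 0, perfect_window)
    }
  })
})

test_that("batch scoring preserves order, averages and skips bad records", {
  primer <- primer_set("probe", "ACGGACCAGG", "forward")
  mk <- function(site) paste0(strrep("T", 15), site, strrep("T", 15))
  perfect <- mk("ACGGACCAGG")
  one_mm <- mk("ATGGACCAGG")  # position 2: non-3' mismatch, 0.4
  records <- tibble::tibble(
    id = sprintf("r%02d", 1:20),
    sequence = c(rep(perfect, 10), rep(one_mm, 10)),
    taxonomy = "Bacteria;P"
  )
  hits <- score_primers(records, primer)
  expect_identical(hits$record_id, records$id)
  expect_equal(mean(hits$weighted_score), 0.20)
  expect_equal(sum(hits$weighted_score == 0), 10L)

  bad <- records
  bad$sequence[3] <- "ACGT!!ACGT"
  expect_warning(hits_bad <- score_primers(bad, primer), "skipping")
  expect_identical(attr(hits_bad, "n_skipped"), 1L)
  expect_identical(nrow(hits_bad), 19L)

  expect_warning(empty <- score_primers(records[0, ], primer), "empty record set")
  expect_identical(nrow(empty), 0L)
})
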