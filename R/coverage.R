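#' Is a sequence amplifiable by a primer pair?
#'
#' A record is predicted amplifiable when both the forward and reverse hit
#' pass the score threshold (weighted or tp score per `config$method`),
#' neither site is truncated, and the forward site lies strictly 5' of the
#' reverse site on the plus strand (overlapping sites do not amplify).
#'
#' @param fwd_hit,rev_hit One-row hit tibbles from [align_primer()] computed
#'   on the same record.
#' @param config A [scoring_config()].
#' @return Logical scalar.
#' @export
sequence_amplifiable <- function(fwd_hit, rev_hit, config = scoring_config()) {
  stopifnot(nrow(fwd_hit) == 1L, nrow(rev_hit) == 1L)
  if (!identical(fwd_hit$record_id, rev_hit$record_id)) {
    stop("forward and reverse hits were computed on different records ('",
         fwd_hit$record_id, "' vs '", rev_hit$record_id, "')", call. = FALSE)
  }
  sc <- if (config$method == "tp") c(fwd_hit$tp_score, rev_hit$tp_score) else
    c(fwd_hit$weighted_score, rev_hit$weighted_score)
  !fwd_hit$truncated && !rev_hit$truncated &&
    all(sc <= config$hit_threshold) &&
    fwd_hit$end < rev_hit$start
}

#' Join forward and reverse hits of a pair by record
#'
#' @param hits Hit table from [score_primers()].
#' @param forward,reverse Primer names of the pair.
#' @return Tibble, one row per record, hit columns prefixed `fwd_`/`rev_`.
#' @export
pair_hit_table <- function(hits, forward, reverse) {
  f <- hits |>
    dplyr::filter(.data$primer_name == forward) |>
    dplyr::rename_with(~ paste0("fwd_", .x), -"record_id")
  r <- hits |>
    dplyr::filter(.data$primer_name == reverse) |>
    dplyr::rename_with(~ paste0("rev_", .x), -"record_id")
  if (nrow(f) == 0L || nrow(r) == 0L) {
    stop("no hits found for primer(s) of pair ", forward, "/", reverse,
         call. = FALSE)
  }
  dplyr::inner_join(f, r, by = "record_id")
}

# per-record pass/truncated/last-base table for a single primer or a pair
.unit_status <- function(hits, config, pair = NULL) {
  thr <- config$hit_threshold
  if (is.null(pair)) {
    sc <- if (config$method == "tp") hits$tp_score else hits$weighted_score
    tibble::tibble(
      unit = hits$primer_name,
      record_id = hits$record_id,
      truncated = hits$truncated,
      pass = !hits$truncated & sc <= thr,
      last_mm = !hits$truncated & hits$last_base_mismatch %in% TRUE
    )
  } else {
    ph <- pair_hit_table(hits, pair[1], pair[2])
    sc_f <- if (config$method == "tp") ph$fwd_tp_score else ph$fwd_weighted_score
    sc_r <- if (config$method == "tp") ph$rev_tp_score else ph$rev_weighted_score
    trunc <- ph$fwd_truncated | ph$rev_truncated
    tibble::tibble(
      unit = paste0(pair[1], "/", pair[2]),
      record_id = ph$record_id,
      truncated = trunc,
      pass = !trunc & sc_f <= thr & sc_r <= thr & ph$fwd_end < ph$rev_start,
      last_mm = !trunc & (ph$fwd_last_base_mismatch %in% TRUE |
                            ph$rev_last_base_mismatch %in% TRUE)
    )
  }
}

#' Per-taxon coverage and non-coverage of primers or a primer pair
#'
#' Aggregates per-record hits into one row per taxon at the requested rank:
#' the number of reference sequences, how many are predicted amplifiable
#' (score at or below `config$hit_threshold`), coverage and non-coverage
#' percentages, and the percentage of sequences whose best site mismatches
#' at the final 3' primer base. For a pair, a record counts as covered only
#' when BOTH primers pass on that same record with correctly ordered sites.
#' Truncated records (shorter than the primer) are excluded from the
#' denominator by default (`config$truncated_policy = "exclude"`), or counted
#' as misses under `"miss"`.
#'
#' @param hits Hit table from [score_primers()].
#' @param records Reference tibble with `id` and `taxonomy`.
#' @param rank Taxonomic rank to aggregate at (name or depth).
#' @param config A [scoring_config()]; `config$method` selects the score.
#' @param pair Optional length-2 character vector `c(forward, reverse)`; when
#'   `NULL`, one set of rows is produced per primer present in `hits`.
#' @return Tibble of class `primer_coverage`, rows sorted by descending
#'   `n_total` within each primer-or-pair, with columns `taxon`, `rank`,
#'   `primer_or_pair`, `n_total`, `n_hit`, `coverage_pct`,
#'   `non_coverage_pct`, `last_base_mm_pct`, `method`.
#' @export
coverage_by_taxon <- function(hits, records, rank = "phylum",
                              config = scoring_config(), pair = NULL) {
  depth <- .rank_depth(rank)
  rank_name <- if (is.character(rank)) tolower(rank) else .RANKS[depth]
  n_ranks <- vapply(strsplit(ifelse(is.na(records$taxonomy), "", records$taxonomy),
                             ";", fixed = TRUE),
                    length, integer(1))
  if (all(n_ranks < depth) && depth > 1L) {
    warning("requested rank '", rank_name,
            "' is deeper than every record's taxonomy", call. = FALSE)
    return(.empty_coverage(rank_name, config$method))
  }
  status <- .unit_status(hits, config, pair)
  status$taxon <- tax_at_rank(
    records$taxonomy[match(status$record_id, records$id)], depth)
  if (config$truncated_policy == "exclude") {
    status <- status[!status$truncated, , drop = FALSE]
  }
  out <- status |>
    dplyr::group_by(.data$unit, .data$taxon) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_hit = sum(.data$pass),
      n_scored = sum(!.data$truncated),
      n_last = sum(.data$last_mm),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rank = rank_name,
      primer_or_pair = .data$unit,
      coverage_pct = 100 * .data$n_hit / .data$n_total,
      non_coverage_pct = 100 * (1 - .data$n_hit / .data$n_total),
      last_base_mm_pct = ifelse(.data$n_scored > 0,
                                100 * .data$n_last / .data$n_scored, NA_real_),
      method = config$method
    ) |>
    dplyr::arrange(.data$primer_or_pair, dplyr::desc(.data$n_total), .data$taxon) |>
    dplyr::select("taxon", "rank", "primer_or_pair", "n_total", "n_hit",
                  "coverage_pct", "non_coverage_pct", "last_base_mm_pct",
                  "method")
  class(out) <- c("primer_coverage", class(out))
  out
}

.empty_coverage <- function(rank_name, method) {
  out <- tibble::tibble(
    taxon = character(), rank = character(), primer_or_pair = character(),
    n_total = integer(), n_hit = integer(),
    coverage_pct = numeric(), non_coverage_pct = numeric(),
    last_base_mm_pct = numeric(), method = character()
  )
  class(out) <- c("primer_coverage", class(out))
  out
}

#' Per-taxon fraction of sequences with a terminal 3' base mismatch
#'
#' For each primer and taxon: 100 x (records whose best site mismatches at
#' the final 3' primer base) / (records with a non-truncated site). Empty
#' groups are omitted.
#'
#' @inheritParams coverage_by_taxon
#' @param group_by Taxonomic rank (name or depth).
#' @return Tibble with `primer_name`, `taxon`, `n`, `last_base_mm_pct`.
#' @export
last_base_mismatch_fraction <- function(hits, records, group_by = "domain") {
  depth <- .rank_depth(group_by)
  h <- hits[!hits$truncated, , drop = FALSE]
  h$taxon <- tax_at_rank(records$taxonomy[match(h$record_id, records$id)], depth)
  h |>
    dplyr::group_by(.data$primer_name, .data$taxon) |>
    dplyr::summarise(
      n = dplyr::n(),
      last_base_mm_pct = 100 * sum(.data$last_base_mismatch) / dplyr::n(),
      .groups = "drop"
    )
}

#' Compare non-coverage under the weighted and total-mismatch methods
#'
#' Computes per-taxon non-coverage twice with the same hits and threshold,
#' once comparing the weighted score and once the tp score, and returns them
#' side by side. With the default weights the weighted method flags terminal
#' 3' mismatches (score 4.0) that the tp method, which scores them 1.0,
#' counts as covered.
#'
#' @inheritParams coverage_by_taxon
#' @return Tibble: `primer_or_pair`, `taxon`, `n_total`,
#'   `non_coverage_weighted`, `non_coverage_tp`.
#' @export
compare_methods <- function(hits, records, rank = "phylum",
                            config = scoring_config(), pair = NULL) {
  cw <- config
  cw$method <- "weighted"
  ct <- config
  ct$method <- "tp"
  w <- coverage_by_taxon(hits, records, rank, cw, pair)
  t <- coverage_by_taxon(hits, records, rank, ct, pair)
  dplyr::inner_join(
    dplyr::select(tibble::as_tibble(w), "primer_or_pair", "taxon", "n_total",
                  non_coverage_weighted = "non_coverage_pct"),
    dplyr::select(tibble::as_tibble(t), "primer_or_pair", "taxon",
                  non_coverage_tp = "non_coverage_pct"),
    by = c("primer_or_pair", "taxon")
  )
}
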