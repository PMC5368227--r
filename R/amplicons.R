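#' Predict amplicons of a primer pair on a reference set
#'
#' Runs the binding-site search for both primers of a pair on every record
#' and emits at most one predicted amplicon per record: the best-scoring
#' forward/reverse site pair with both scores at or below the threshold and
#' the forward site 5' of the reverse site. The amplicon spans the forward
#' primer's 5' end through the plus-strand image of the reverse primer's 5'
#' end, both primer sites included; coordinates are 1-based inclusive.
#' Records whose sites overlap are skipped with a warning tally (attribute
#' `n_overlapping`).
#'
#' @param records Reference tibble (`id`, `sequence`, optional `taxonomy`).
#' @param fwd,rev One-row primer tibbles (forward / reverse orientation).
#' @param config A [scoring_config()].
#' @param hits Optional precomputed hit table for both primers (saves
#'   re-alignment).
#' @return Tibble of class `amplicon_tbl`: `record_id`, `start`, `end`,
#'   `length`, `taxonomy`.
#' @export
extract_amplicons <- function(records, fwd, rev, config = scoring_config(),
                              hits = NULL) {
  stopifnot(identical(fwd$orientation, "forward"),
            identical(rev$orientation, "reverse"))
  if (is.null(hits)) {
    hits <- score_primers(records, dplyr::bind_rows(fwd, rev), config)
  }
  ph <- pair_hit_table(hits, fwd$name, rev$name)
  thr <- config$hit_threshold
  sc_f <- if (config$method == "tp") ph$fwd_tp_score else ph$fwd_weighted_score
  sc_r <- if (config$method == "tp") ph$rev_tp_score else ph$rev_weighted_score
  both_pass <- !ph$fwd_truncated & !ph$rev_truncated & sc_f <= thr & sc_r <= thr
  ordered <- ph$fwd_end < ph$rev_start
  n_overlap <- sum(both_pass & !ordered, na.rm = TRUE)
  if (n_overlap > 0L) {
    warning(n_overlap, " record(s) with overlapping or misordered primer ",
            "sites yielded no amplicon", call. = FALSE)
  }
  keep <- which(both_pass & ordered)
  out <- tibble::tibble(
    record_id = ph$record_id[keep],
    start = ph$fwd_start[keep],
    end = ph$rev_end[keep],
    length = ph$rev_end[keep] - ph$fwd_start[keep] + 1L,
    taxonomy = if ("taxonomy" %in% names(records)) {
      records$taxonomy[match(ph$record_id[keep], records$id)]
    } else {
      NA_character_
    }
  )
  attr(out, "n_overlapping") <- n_overlap
  attr(out, "pair") <- paste0(fwd$name, "/", rev$name)
  class(out) <- c("amplicon_tbl", class(out))
  out
}

#' Amplicon length histogram by taxon
#'
#' Bins predicted amplicon lengths per taxon; counts are conserved across
#' bin widths. Bins are left-closed intervals starting at
#' `bin_width * floor(length / bin_width)`.
#'
#' @param amplicons Tibble from [extract_amplicons()].
#' @param group_by Taxonomic rank (name or depth).
#' @param bin_width Bin width in bases.
#' @return Tibble of class `amplicon_length_dist`: `taxon`, `bin_start`,
#'   `count`.
#' @export
length_distribution <- function(amplicons, group_by = "phylum", bin_width = 1L) {
  stopifnot(bin_width >= 1L)
  depth <- .rank_depth(group_by)
  out <- amplicons |>
    tibble::as_tibble() |>
    dplyr::mutate(
      taxon = tax_at_rank(.data$taxonomy, depth),
      bin_start = as.integer(bin_width * (.data$length %/% bin_width))
    ) |>
    dplyr::count(.data$taxon, .data$bin_start, name = "count") |>
    dplyr::arrange(.data$taxon, .data$bin_start)
  attr(out, "bin_width") <- as.integer(bin_width)
  class(out) <- c("amplicon_length_dist", class(out))
  out
}

#' Modal amplicon length per taxon
#'
#' @inheritParams length_distribution
#' @return Tibble: `taxon`, `modal_length`, `n_at_mode`, `n`.
#' @export
length_modes <- function(amplicons, group_by = "phylum") {
  depth <- .rank_depth(group_by)
  amplicons |>
    tibble::as_tibble() |>
    dplyr::mutate(taxon = tax_at_rank(.data$taxonomy, depth)) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      modal_length = {
        tb <- table(.data$length)
        as.integer(names(tb)[which.max(tb)])
      },
      n_at_mode = max(table(.data$length)),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Write predicted amplicon sequences as FASTA
#'
#' @param amplicons Tibble from [extract_amplicons()].
#' @param records The reference tibble the amplicons were derived from.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_amplicons_fasta <- function(amplicons, records, path) {
  seqs <- substr(records$sequence[match(amplicons$record_id, records$id)],
                 amplicons$start, amplicons$end)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- paste0(amplicons$record_id, " ",
                      amplicons$start, "-", amplicons$end)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
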