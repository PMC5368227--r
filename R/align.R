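#' 3'-weighted primer binding-site score
#'
#' Applies the weighted-score formula to categorised mismatch/gap counts:
#' `non3p_mm * w_non3p_mm + threep_mm * w_3p_mm + non3p_gap * w_non3p_gap +
#' threep_gap * w_3p_gap`, plus `terminal_penalty` when the final 3' base of
#' the primer is an aligned mismatch. Lower is better; 0 is a perfect site.
#'
#' @param non3p_mm,threep_mm Mismatch counts outside / inside the 3' region.
#' @param non3p_gap,threep_gap Gap counts outside / inside the 3' region.
#' @param last_base_mismatch Logical: does the final 3' base mismatch?
#' @param config A [scoring_config()].
#' @return Non-negative numeric score (vectorised).
#' @examples
#' weighted_score(1, 0, 0, 0)            # 0.40
#' weighted_score(0, 1, 0, 0, TRUE)      # 4.00
#' @export
weighted_score <- function(non3p_mm, threep_mm, non3p_gap, threep_gap,
                           last_base_mismatch = FALSE,
                           config = scoring_config()) {
  counts <- cbind(non3p_mm, threep_mm, non3p_gap, threep_gap)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative", call. = FALSE)
  non3p_mm * config$w_non3p_mm + threep_mm * config$w_3p_mm +
    non3p_gap * config$w_non3p_gap + threep_gap * config$w_3p_gap +
    config$terminal_penalty * as.numeric(last_base_mismatch)
}

#' Total-mismatch ("tp") primer score
#'
#' Position-agnostic unit-weight count of all mismatches plus all gaps, with
#' no terminal-base penalty. Compared with the weighted score it penalises 3'
#' defects far less: a single terminal 3' mismatch scores 1.0 here but 4.0
#' under the default weighted score.
#'
#' @param total_mismatches,total_gaps Non-negative counts (vectorised).
#' @return Numeric score.
#' @export
tp_score <- function(total_mismatches, total_gaps = 0) {
  if (any(c(total_mismatches, total_gaps) < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  total_mismatches * 1.0 + total_gaps * 1.0
}

# ungapped weighted score at every offset (vectorised; used by the search
# and by the synthetic generator's background-repair pre-pass)
.ungapped_scan <- function(p_codes, t_codes, cfg) {
  L <- length(p_codes)
  n <- length(t_codes) - L + 1L
  if (n < 1L) return(numeric(0))
  tpl <- min(cfg$three_prime_len, L)
  is3p <- seq_len(L) > L - tpl
  w <- ifelse(is3p, cfg$w_3p_mm, cfg$w_non3p_mm)
  mm <- matrix(FALSE, n, L)
  for (i in seq_len(L)) {
    mm[, i] <- !.iupac_match_matrix[p_codes[i], t_codes[i:(i + n - 1L)]]
  }
  as.numeric(mm %*% w) + cfg$terminal_penalty * mm[, L]
}

# Best binding site of an encoded primer on an encoded template.
#
# Two-stage search: a vectorised scan of every ungapped offset, then (when a
# gapped alignment could possibly score lower) an exact fitting-alignment DP
# over the whole template with a gap-count dimension 0..max_gaps. The DP
# therefore minimises the weighted score over ALL placements of at most
# max_gaps indels at every offset. Ties prefer ungapped sites, then the site
# closest to `target_start` (the primer's expected reference position) when
# given, then the leftmost site.
.align_codes <- function(p, t, cfg, target_start = NA_integer_) {
  L <- length(p)
  Tn <- length(t)
  if (Tn < L) {
    return(list(score = Inf, non3p_mm = NA_integer_, threep_mm = NA_integer_,
                non3p_gap = NA_integer_, threep_gap = NA_integer_,
                last_base_mismatch = NA, start = NA_integer_, end = NA_integer_,
                truncated = TRUE))
  }
  tpl <- min(cfg$three_prime_len, L)
  is3p <- seq_len(L) > L - tpl
  mmw <- ifelse(is3p, cfg$w_3p_mm, cfg$w_non3p_mm)
  gapw <- ifelse(is3p, cfg$w_3p_gap, cfg$w_non3p_gap)
  insw <- if (L >= 2L) gapw[2:L] else numeric(0)  # insertion in slot i ~ position i+1

  n_off <- Tn - L + 1L
  mm <- matrix(FALSE, n_off, L)
  for (i in seq_len(L)) {
    mm[, i] <- !.iupac_match_matrix[p[i], t[i:(i + n_off - 1L)]]
  }
  scores_u <- as.numeric(mm %*% mmw) + cfg$terminal_penalty * mm[, L]
  best_u <- min(scores_u)

  pick_offset <- function(cands) {
    if (!is.na(target_start)) {
      d <- abs(cands - target_start)
      cands <- cands[d == min(d)]
    }
    cands[1]
  }
  off <- pick_offset(which(scores_u <= best_u + 1e-9))

  result <- list(
    score = best_u,
    non3p_mm = sum(mm[off, ] & !is3p),
    threep_mm = sum(mm[off, ] & is3p),
    non3p_gap = 0L, threep_gap = 0L,
    last_base_mismatch = mm[off, L],
    start = off, end = off + L - 1L,
    truncated = FALSE
  )

  G <- cfg$max_gaps
  min_gap_cost <- if (G > 0L) min(c(gapw, insw)) else Inf
  if (G > 0L && best_u > min_gap_cost + 1e-9) {
    gp <- .fit_gapped(p, t, cfg, is3p, mmw, gapw, insw, target_start)
    if (!is.null(gp) && gp$score < best_u - 1e-9) {
      result <- c(gp, list(truncated = FALSE))
    }
  }
  result
}

# Fitting alignment (primer global, template ends free) minimising the
# weighted score, with at most max_gaps indels. Returns NULL when no gapped
# alignment exists, else the best alignment's score, categorised counts and
# template coordinates (recovered by traceback).
.fit_gapped <- function(p, t, cfg, is3p, mmw, gapw, insw, target_start) {
  L <- length(p)
  Tn <- length(t)
  G <- cfg$max_gaps
  if (L < 1L) return(NULL)

  # D[i+1, j+1, g+1]: min cost aligning primer[1..i] ending at template pos j
  # (leading template free) using exactly the recorded transitions, g gaps
  D <- array(Inf, dim = c(L + 1L, Tn + 1L, G + 1L))
  D[1, , 1] <- 0

  subcost <- vector("list", L)
  for (i in seq_len(L)) {
    mrow <- .iupac_match_matrix[p[i], t]
    subcost[[i]] <- ifelse(mrow, 0,
                           mmw[i] + if (i == L) cfg$terminal_penalty else 0)
  }

  for (i in seq_len(L)) {
    for (g in 0:G) {
      diag <- D[i, 1:Tn, g + 1L] + subcost[[i]]
      # a deletion gap is never placed at the terminal 3' base (i == L):
      # extension requires the primer terminus to be base-paired
      if (g > 0L && i < L) {
        del <- D[i, , g] + gapw[i]
        D[i + 1L, 1L, g + 1L] <- del[1L]
        D[i + 1L, 2:(Tn + 1L), g + 1L] <- pmin(diag, del[2:(Tn + 1L)])
      } else {
        D[i + 1L, 2:(Tn + 1L), g + 1L] <- diag
      }
    }
    if (i < L) {
      for (g in seq_len(G)) {
        ins <- D[i + 1L, 1:Tn, g] + insw[i]
        D[i + 1L, 2:(Tn + 1L), g + 1L] <-
          pmin(D[i + 1L, 2:(Tn + 1L), g + 1L], ins)
      }
    }
  }

  final <- D[L + 1L, , , drop = FALSE]
  best <- min(final)
  if (!is.finite(best)) return(NULL)

  # best end cell: smallest gap count, then end nearest the expected site
  hits <- which(final <= best + 1e-9, arr.ind = TRUE)
  hits <- hits[order(hits[, 3], decreasing = FALSE), , drop = FALSE]
  g_min <- hits[1, 3]
  hits <- hits[hits[, 3] == g_min, , drop = FALSE]
  ends <- hits[, 2] - 1L
  if (!is.na(target_start)) {
    d <- abs(ends - (target_start + L - 1L))
    ends <- ends[d == min(d)]
  }
  j <- min(ends)
  g <- g_min - 1L

  # traceback, recomputing transition costs
  i <- L
  counts <- c(non3p_mm = 0L, threep_mm = 0L, non3p_gap = 0L, threep_gap = 0L)
  last_mm <- FALSE
  end_pos <- j
  val <- D[i + 1L, j + 1L, g + 1L]
  tol <- 1e-9
  while (i > 0L) {
    if (i < L && g > 0L && j > 0L &&
        abs(D[i + 1L, j, g] + insw[i] - val) < tol) {
      k <- if (is3p[i + 1L]) "threep_gap" else "non3p_gap"
      counts[k] <- counts[k] + 1L
      j <- j - 1L; g <- g - 1L
    } else if (j > 0L && abs(D[i, j, g + 1L] + subcost[[i]][j] - val) < tol) {
      if (subcost[[i]][j] > 0) {
        k <- if (is3p[i]) "threep_mm" else "non3p_mm"
        counts[k] <- counts[k] + 1L
        if (i == L) last_mm <- TRUE
      }
      i <- i - 1L; j <- j - 1L
    } else if (g > 0L && i < L && abs(D[i, j + 1L, g] + gapw[i] - val) < tol) {
      k <- if (is3p[i]) "threep_gap" else "non3p_gap"
      counts[k] <- counts[k] + 1L
      i <- i - 1L; g <- g - 1L
    } else {
      stop("internal error: alignment traceback failed", call. = FALSE)
    }
    val <- D[i + 1L, j + 1L, g + 1L]
  }

  list(score = best,
       non3p_mm = counts[["non3p_mm"]], threep_mm = counts[["threep_mm"]],
       non3p_gap = counts[["non3p_gap"]], threep_gap = counts[["threep_gap"]],
       last_base_mismatch = last_mm,
       start = j + 1L, end = end_pos)
}

.primer_row <- function(primer) {
  if (is.character(primer) && length(primer) == 1L) {
    return(primer_set(name = primer, sequence = primer, orientation = "forward"))
  }
  stopifnot(is.data.frame(primer), nrow(primer) == 1L)
  primer
}

#' Locate the best binding site of a primer on one template
#'
#' Scans every ungapped offset and, when it could improve the score, every
#' gapped placement with at most `config$max_gaps` indels, and returns the
#' site with the minimum weighted score. The primer's 3' terminal base must
#' always be base-paired: no gap is ever placed at the final primer position
#' (an unpaired 3' terminus cannot be extended by the polymerase), so the
#' terminal penalty applies exactly when that aligned final base mismatches.
#' Reverse primers are matched against
#' the reverse complement of the template and coordinates are mapped back to
#' the plus strand. Deterministic for fixed inputs; ties prefer ungapped
#' sites, then the site closest to the primer's E. coli coordinates when the
#' template spans them, then the leftmost site.
#'
#' @param primer One-row primer tibble (see [primer_set()]) or a plain IUPAC
#'   string (treated as a forward primer).
#' @param template Template sequence (IUPAC string; `U` converted to `T`).
#' @param config A [scoring_config()].
#' @param record_id Optional record identifier carried into the result.
#' @return One-row tibble: `primer_name`, `record_id`, categorised
#'   mismatch/gap counts, `last_base_mismatch`, `weighted_score`, `tp_score`,
#'   1-based inclusive plus-strand `start`/`end`, and `truncated` (template
#'   shorter than the primer; such records carry an infinite score and are
#'   never hits).
#' @examples
#' align_primer("ACGT", "TTACGTTT", scoring_config(three_prime_len = 2))
#' @export
align_primer <- function(primer, template, config = scoring_config(),
                         record_id = NA_character_) {
  primer <- .primer_row(primer)
  t_seq <- clean_sequence(template)
  t_codes <- .encode_seq(t_seq)
  .align_encoded(primer, t_codes, config, record_id)
}

# primer: one-row tibble; t_codes: encoded plus-strand template
.align_encoded <- function(primer, t_codes, config, record_id) {
  p_codes <- .encode_seq(primer$sequence)
  Tn <- length(t_codes)
  L <- length(p_codes)
  reverse <- identical(primer$orientation, "reverse")
  spans_ref <- !is.na(primer$ecoli_end) && Tn >= primer$ecoli_end
  if (reverse) {
    t_work <- rev(.IUPAC_COMP_IDX[t_codes])
    target <- if (spans_ref) Tn - primer$ecoli_end + 1L else NA_integer_
  } else {
    t_work <- t_codes
    target <- if (spans_ref) primer$ecoli_start else NA_integer_
  }
  a <- .align_codes(p_codes, t_work, config, target_start = target)
  if (reverse && !a$truncated) {
    s <- Tn - a$end + 1L
    e <- Tn - a$start + 1L
    a$start <- s
    a$end <- e
  }
  total_mm <- a$non3p_mm + a$threep_mm
  total_gap <- a$non3p_gap + a$threep_gap
  tibble::tibble(
    primer_name = primer$name,
    record_id = record_id,
    non3p_mismatches = a$non3p_mm,
    threep_mismatches = a$threep_mm,
    non3p_gaps = a$non3p_gap,
    threep_gaps = a$threep_gap,
    last_base_mismatch = a$last_base_mismatch,
    weighted_score = a$score,
    tp_score = if (is.finite(a$score)) tp_score(total_mm, total_gap) else Inf,
    start = a$start,
    end = a$end,
    truncated = a$truncated
  )
}

#' Score a primer set against a reference set
#'
#' Runs [align_primer()] for every primer on every reference record and
#' returns the hits as one tidy table, one row per primer x record,
#' order-preserving. Records whose sequence cannot be parsed are skipped with
#' a warning; the number skipped is attached as attribute `n_skipped`.
#'
#' @param records Reference tibble with columns `id` and `sequence` (see
#'   [read_silva_fasta()]).
#' @param primers Primer tibble, one or more rows.
#' @param config A [scoring_config()].
#' @param verbose Log progress to stderr every `progress_every` records.
#' @param progress_every Integer interval for progress messages.
#' @return Tibble of primer hits.
#' @export
score_primers <- function(records, primers, config = scoring_config(),
                          verbose = FALSE, progress_every = 1000L) {
  stopifnot(is.data.frame(records), is.data.frame(primers))
  if (nrow(records) == 0L) {
    warning("empty record set: no hits computed", call. = FALSE)
    out <- .align_encoded(primers[1, , drop = FALSE], .encode_seq("ACGT"),
                          config, "x")[0, ]
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  enc <- vector("list", nrow(records))
  ok <- logical(nrow(records))
  for (r in seq_len(nrow(records))) {
    enc[[r]] <- tryCatch(.encode_seq(clean_sequence(records$sequence[r])),
                         error = function(e) NULL)
    ok[r] <- !is.null(enc[[r]])
    if (!ok[r]) {
      warning("skipping unreadable record '", records$id[r], "': ",
              "invalid sequence", call. = FALSE)
    }
  }
  rows <- vector("list", nrow(primers))
  for (k in seq_len(nrow(primers))) {
    prm <- primers[k, , drop = FALSE]
    hit_list <- vector("list", sum(ok))
    idx <- which(ok)
    for (m in seq_along(idx)) {
      r <- idx[m]
      hit_list[[m]] <- .align_encoded(prm, enc[[r]], config, records$id[r])
      if (verbose && m %% progress_every == 0L) {
        message(prm$name, ": ", m, "/", length(idx), " records scored")
      }
    }
    rows[[k]] <- dplyr::bind_rows(hit_list)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_skipped") <- sum(!ok)
  out
}
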