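#' Scoring configuration for primer binding-site evaluation
#'
#' Parameters of the 3'-weighted score. The weighted score of a binding site
#' is
#' \deqn{0.40 \cdot mm_{non3'} + 1.00 \cdot mm_{3'} + 1.00 \cdot gap_{non3'}
#'   + 3.00 \cdot gap_{3'} (+\,3.00\ \mathrm{if\ the\ final\ base\ mismatches})}
#' with the default weights below; the 3' region is the final
#' `three_prime_len` bases of the primer. The total-mismatch ("tp") score is
#' the unit-weight count of all mismatches plus gaps. A site is counted
#' amplifiable when its score (per `method`) is at most `hit_threshold`.
#'
#' @param three_prime_len Bases at the primer 3' end treated as the 3' region.
#' @param w_non3p_mm,w_3p_mm Penalty per mismatch outside / inside the 3' region.
#' @param w_non3p_gap,w_3p_gap Penalty per gap outside / inside the 3' region.
#' @param terminal_penalty Extra penalty when the final 3' base is an aligned
#'   base-base mismatch (a gap at the final base does not trigger it).
#' @param hit_threshold Maximum score still counted as amplifiable.
#' @param max_gaps Gap budget of the binding-site search (0 disables gapped
#'   alignment).
#' @param method Which score the coverage calculations compare to
#'   `hit_threshold`: `"weighted"` or `"tp"`.
#' @param truncated_policy How coverage denominators treat records shorter
#'   than the primer: `"exclude"` (default) drops them from the denominator,
#'   `"miss"` counts them as non-covered.
#' @return A list with class `scoring_config`.
#' @export
scoring_config <- function(three_prime_len = 5L,
                           w_non3p_mm = 0.40, w_3p_mm = 1.00,
                           w_non3p_gap = 1.00, w_3p_gap = 3.00,
                           terminal_penalty = 3.00,
                           hit_threshold = 1.0,
                           max_gaps = 2L,
                           method = c("weighted", "tp"),
                           truncated_policy = c("exclude", "miss")) {
  method <- match.arg(method)
  truncated_policy <- match.arg(truncated_policy)
  three_prime_len <- as.integer(three_prime_len)
  max_gaps <- as.integer(max_gaps)
  weights <- c(w_non3p_mm, w_3p_mm, w_non3p_gap, w_3p_gap, terminal_penalty)
  if (any(weights < 0)) stop("all penalty weights must be >= 0", call. = FALSE)
  if (three_prime_len < 0L) stop("three_prime_len must be >= 0", call. = FALSE)
  if (max_gaps < 0L) stop("max_gaps must be >= 0", call. = FALSE)
  structure(
    list(three_prime_len = three_prime_len,
         w_non3p_mm = w_non3p_mm, w_3p_mm = w_3p_mm,
         w_non3p_gap = w_non3p_gap, w_3p_gap = w_3p_gap,
         terminal_penalty = terminal_penalty,
         hit_threshold = hit_threshold,
         max_gaps = max_gaps,
         method = method,
         truncated_policy = truncated_policy),
    class = "scoring_config"
  )
}

#' Construct a primer table
#'
#' @param name Primer names (e.g. `"341f"`).
#' @param sequence IUPAC sequences written 5' to 3'.
#' @param orientation `"forward"` or `"reverse"`. A reverse primer as written
#'   anneals to the reverse complement of the plus strand.
#' @param ecoli_start,ecoli_end Optional 1-based inclusive binding positions
#'   on the E. coli 16S reference gene, the community coordinate convention.
#' @return A tibble with one row per primer.
#' @export
primer_set <- function(name, sequence, orientation,
                       ecoli_start = NA_integer_, ecoli_end = NA_integer_) {
  sequence <- vapply(sequence, clean_sequence, character(1), USE.NAMES = FALSE)
  orientation <- match.arg(orientation, c("forward", "reverse"), several.ok = TRUE)
  out <- tibble::tibble(
    name = as.character(name),
    sequence = sequence,
    orientation = rep_len(orientation, length(name)),
    ecoli_start = as.integer(ecoli_start),
    ecoli_end = as.integer(ecoli_end)
  )
  bad <- !is.na(out$ecoli_start) & !is.na(out$ecoli_end) &
    nchar(out$sequence) != out$ecoli_end - out$ecoli_start + 1L
  if (any(bad)) {
    stop("primer length disagrees with reference coordinates for: ",
         paste(out$name[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' The packaged bacteria-specific 16S primer set
#'
#' Eight commonly used bacteria-specific 16S rRNA gene primers (four pairs:
#' 68f/518r, 341f/785r, 799f/1193r, 967f/1391r) with their IUPAC sequences
#' and E. coli binding coordinates, read from the TSV shipped with the
#' package.
#'
#' @return Tibble of primers, with a `pair` column naming each primer pair.
#' @export
default_primers <- function() {
  path <- system.file("extdata", "primers_16s.tsv", package = "primerscout")
  read_primers(path)
}

#' Read primer definitions from TSV or YAML
#'
#' TSV columns: `name`, `sequence`, `orientation`, optional `ecoli_start`,
#' `ecoli_end`, `pair`. A YAML file holds a list of mappings with the same
#' keys.
#'
#' @param path File path; format chosen by extension (`.yml`/`.yaml` vs TSV).
#' @return Tibble of primers.
#' @export
read_primers <- function(path) {
  if (!file.exists(path)) stop("primer file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    df <- dplyr::bind_rows(lapply(raw, tibble::as_tibble))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    df <- tibble::as_tibble(df)
  }
  need <- c("name", "sequence", "orientation")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("primer file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- primer_set(
    name = df$name, sequence = df$sequence, orientation = df$orientation,
    ecoli_start = if ("ecoli_start" %in% names(df)) df$ecoli_start else NA_integer_,
    ecoli_end = if ("ecoli_end" %in% names(df)) df$ecoli_end else NA_integer_
  )
  if ("pair" %in% names(df)) out$pair <- as.character(df$pair)
  out
}

#' Primer pairs of a primer table
#'
#' @param primers A primer tibble with a `pair` column (as from
#'   [default_primers()]).
#' @return Tibble with columns `pair`, `forward`, `reverse`.
#' @export
primer_pairs <- function(primers = default_primers()) {
  if (!"pair" %in% names(primers)) stop("primer table has no 'pair' column", call. = FALSE)
  primers |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      forward = .data$name[.data$orientation == "forward"][1],
      reverse = .data$name[.data$orientation == "reverse"][1],
      .groups = "drop"
    )
}

.get_primer <- function(primers, name) {
  row <- primers[primers$name == name, , drop = FALSE]
  if (nrow(row) != 1L) stop("primer '", name, "' not found (or duplicated)", call. = FALSE)
  row
}
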