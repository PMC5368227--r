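#' Plot per-taxon non-coverage
#'
#' Horizontal bar chart of non-coverage percentage per taxon, facetted by
#' primer-or-pair (and by method when several are present), the usual way
#' primer evaluations are compared across a reference database.
#'
#' @param object A `primer_coverage` table from [coverage_by_taxon()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.primer_coverage <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$non_coverage_pct,
    y = stats::reorder(.data$taxon, .data$n_total),
    fill = .data$primer_or_pair)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Non-coverage (%)", y = NULL, fill = "Primer / pair") +
    ggplot2::theme_minimal()
  if (length(unique(df$method)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$method))
  }
  p
}

#' Plot an amplicon length distribution
#'
#' Stacked histogram of predicted amplicon lengths coloured by taxon;
#' length polymorphisms between the primer sites show up as separated
#' peaks.
#'
#' @param object An `amplicon_length_dist` from [length_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amplicon_length_dist <- function(object, ...) {
  bw <- attr(object, "bin_width") %||% 1L
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$bin_start + bw / 2, y = .data$count, fill = .data$taxon)) +
    ggplot2::geom_col(width = bw) +
    ggplot2::labs(x = "Amplicon length (nt)", y = "Sequences", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot weighted versus total-mismatch non-coverage
#'
#' Paired-point plot of per-taxon non-coverage under the two scoring
#' methods, highlighting taxa the weighted score flags (3' defects) that
#' the unit-weight total-mismatch score lets pass.
#'
#' @param comparison Output of [compare_methods()].
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(comparison) {
  df <- tidyr::pivot_longer(comparison,
                            cols = c("non_coverage_weighted", "non_coverage_tp"),
                            names_to = "method", names_prefix = "non_coverage_",
                            values_to = "non_coverage_pct")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$non_coverage_pct,
    y = .data$taxon,
    colour = .data$method)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$primer_or_pair)) +
    ggplot2::labs(x = "Non-coverage (%)", y = NULL, colour = "Score") +
    ggplot2::theme_minimal()
}
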