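#' qPCR amplification efficiency from a standard-curve slope
#'
#' Converts the fitted slope of a Cq versus log10(template quantity)
#' dilution series into percent amplification efficiency:
#' \deqn{E = (10^{-1/slope} - 1) \times 100.}
#' A slope of \eqn{-1/\log_{10} 2 \approx -3.3219} corresponds to perfect
#' doubling per cycle (100%).
#'
#' @param slope Fitted slope; must be negative for a valid dilution series.
#' @return Efficiency in percent (vectorised).
#' @examples
#' pcr_efficiency(-1 / log10(2))  # 100
#' @export
pcr_efficiency <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0)) {
    stop("dilution series slope must be negative", call. = FALSE)
  }
  (10^(-1 / slope) - 1) * 100
}

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of Cq against log10 template quantity, the
#' standard dilution-series calibration, with the amplification efficiency
#' derived from the slope via [pcr_efficiency()].
#'
#' @param data Data frame of the dilution series.
#' @param cq,quantity Column names (strings) holding the quantification
#'   cycle and the template quantity (copies or ng; log10 is applied here).
#' @return Object of class `qpcr_curve`: the `lm` fit plus `slope`,
#'   `intercept` and `efficiency_pct`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_standard_curve <- function(data, cq = "cq", quantity = "quantity") {
  stopifnot(is.data.frame(data), cq %in% names(data), quantity %in% names(data))
  df <- data.frame(cq = data[[cq]], lq = log10(data[[quantity]]))
  fit <- stats::lm(cq ~ lq, data = df)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("dilution series slope must be negative", call. = FALSE)
  }
  structure(
    list(fit = fit, slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         efficiency_pct = pcr_efficiency(slope),
         n = nrow(df)),
    class = "qpcr_curve"
  )
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat("qPCR standard curve (n =", x$n, "points)\n")
  cat(sprintf("  slope: %.4f   intercept: %.3f\n", x$slope, x$intercept))
  cat(sprintf("  efficiency: %.2f%%\n", x$efficiency_pct))
  invisible(x)
}

#' Tidy a qPCR standard-curve fit
#'
#' @param x A `qpcr_curve`.
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.qpcr_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "log10(quantity)"),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' One-row summary of a qPCR standard-curve fit
#'
#' @param x A `qpcr_curve`.
#' @param ... Unused.
#' @return One-row tibble: `slope`, `intercept`, `efficiency_pct`,
#'   `r.squared`, `n`.
#' @export
glance.qpcr_curve <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    efficiency_pct = x$efficiency_pct,
    r.squared = summary(x$fit)$r.squared,
    n = x$n
  )
}
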