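# Absolute quantification front-end: dilution-series standard curve mapping
# Cq values to copy numbers. Optional -- pipelines may ingest copy numbers
# directly.

#' Build a qPCR dilution series
#'
#' A dilution series for absolute quantification: each level is a known
#' dilution of a stock of known copy number, measured in one or more Cq
#' replicates. The classic scheme here is a first 2/7 dilution followed by
#' two ten-fold dilutions, giving factors 1, 2/7, 2/70, 2/700 relative to the
#' stock.
#'
#' @param dilution_factor Numeric vector, one entry per Cq observation: the
#'   concentration of that observation relative to the stock (in (0, 1]).
#' @param cq Numeric vector of Cq values, same length.
#' @param stock_copies Copies per reaction in the undiluted stock (> 0).
#'
#' @return An object of class `dilution_series` with a `copies` column
#'   (`stock_copies * dilution_factor`).
#' @export
dilution_series <- function(dilution_factor, cq, stock_copies) {
  if (length(dilution_factor) != length(cq))
    stop("dilution_factor and cq must have the same length", call. = FALSE)
  if (any(dilution_factor <= 0) || any(dilution_factor > 1))
    stop("dilution factors must lie in (0, 1]", call. = FALSE)
  if (length(stock_copies) != 1L || stock_copies <= 0)
    stop("stock_copies must be a single positive number", call. = FALSE)
  if (!all(is.finite(cq))) stop("Cq values must be finite", call. = FALSE)
  structure(
    list(
      data = data.frame(dilution_factor = dilution_factor, cq = cq,
                        copies = stock_copies * dilution_factor),
      stock_copies = stock_copies
    ),
    class = "dilution_series"
  )
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies) over all replicate points of
#' a dilution series. Amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1` (a slope of -3.3219 = -1/log10(2) corresponds to
#' perfect doubling, efficiency 1). A non-monotone mean Cq across
#' concentration levels is reported via the `monotone` field and a warning,
#' not an error.
#'
#' @param series A [dilution_series()] with at least 3 distinct levels.
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept` (Cq at 1 copy), `efficiency`, `r_squared`, `n_levels`,
#'   `monotone`.
#' @export
fit_standard_curve <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  d <- series$data
  if (length(unique(d$dilution_factor)) < 3L)
    stop("at least 3 dilution levels are required to fit a standard curve",
         call. = FALSE)
  fit <- stats::lm(cq ~ log10(copies), data = d)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("standard curve slope must be negative (Cq decreases with copies)",
         call. = FALSE)
  mean_cq <- tapply(d$cq, d$copies, mean)
  # mean Cq must decrease as copies increase
  monotone <- all(diff(mean_cq[order(as.numeric(names(mean_cq)))]) < 0)
  if (!monotone)
    warning("mean Cq is not monotone decreasing in concentration",
            call. = FALSE)
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         efficiency = 10^(-1 / slope) - 1,
         r_squared = .lm_summary(fit)$r.squared,
         n_levels = length(unique(d$dilution_factor)),
         monotone = monotone),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: slope %.4f, intercept %.2f, efficiency %.1f%%, R^2 %.4f\n",
    x$slope, x$intercept, 100 * x$efficiency, x$r_squared))
  if (!x$monotone) cat("  warning: non-monotone mean Cq across levels\n")
  invisible(x)
}

#' Convert Cq values to absolute copy numbers
#'
#' Inverts the standard curve: `copies = 10^((cq - intercept)/slope)`.
#' Replicate Cq values for one sample should be averaged arithmetically
#' before conversion (Cq is a log-domain quantity, so this is a geometric
#' mean of copies); `aggregate_cq()` does this.
#'
#' @param cq Numeric vector of Cq values.
#' @param curve A fitted [fit_standard_curve()] object.
#' @return Copy numbers, strictly decreasing in Cq.
#' @export
copies_from_cq <- function(cq, curve) {
  if (!inherits(curve, "standard_curve"))
    stop("curve must be a fitted standard_curve", call. = FALSE)
  if (any(!is.finite(cq))) stop("Cq values must be finite", call. = FALSE)
  10^((cq - curve$intercept) / curve$slope)
}

#' Predicted Cq for a given copy number
#'
#' @param copies Copy numbers (> 0).
#' @param curve A fitted [fit_standard_curve()] object.
#' @return Predicted Cq values.
#' @export
predict_cq <- function(copies, curve) {
  if (!inherits(curve, "standard_curve"))
    stop("curve must be a fitted standard_curve", call. = FALSE)
  if (any(copies <= 0)) stop("copies must be positive", call. = FALSE)
  curve$intercept + curve$slope * log10(copies)
}

#' Arithmetic mean of replicate Cq values
#'
#' @param cq Numeric vector of replicate Cq values for one sample.
#' @return Single aggregated Cq.
#' @export
aggregate_cq <- function(cq) mean(cq)
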