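# Per-temperature estimation of the first-order per-nucleotide cut rate k_T
# from time series of P_uncut.
#
# Model: P_uncut(t) = e^(-k t), so -ln P_uncut is linear in t with slope k
# and zero intercept. The default fit is a least-squares line through the
# origin in that log domain; an unconstrained variant (free intercept) is
# available as a config switch.

#' Assemble a per-temperature kinetic series
#'
#' @param temperature_c Temperature of the series in degrees Celsius.
#' @param time_s Times in seconds (>= 0).
#' @param p_uncut Per-position survival estimates at those times.
#' @param capsule_id Optional capsule identifiers (recycled if length 1).
#'
#' @return An object of class `kinetic_series`.
#' @export
kinetic_series <- function(temperature_c, time_s, p_uncut,
                           capsule_id = NA_character_) {
  if (length(time_s) != length(p_uncut))
    stop("time_s and p_uncut must have the same length", call. = FALSE)
  if (any(time_s < 0)) stop("times must be non-negative", call. = FALSE)
  d <- data.frame(time_s = time_s, p_uncut = p_uncut,
                  capsule_id = capsule_id)
  d <- d[order(d$time_s), , drop = FALSE]
  structure(
    list(temperature_c = temperature_c, points = d,
         n_capsules = length(unique(stats::na.omit(d$capsule_id)))),
    class = "kinetic_series"
  )
}

#' @export
print.kinetic_series <- function(x, ...) {
  cat(sprintf("Kinetic series at %g degC: %d points, %d capsule(s)\n",
              x$temperature_c, nrow(x$points), max(1L, x$n_capsules)))
  invisible(x)
}

# summary.lm warns on noiseless data; that case is legitimate here
.lm_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Fit the first-order cut rate constant for one temperature
#'
#' Regresses `-ln(p_uncut)` on time. With `method = "origin"` (default) the
#' line is constrained through the origin, enforcing `P_uncut(0) = 1` as the
#' random-breakage model requires; `method = "free"` fits an unconstrained
#' intercept. Survival estimates above 1 contribute negative `-ln p` and are
#' retained: discarding or clamping them would bias the rate upward.
#' A negative fitted rate (possible under noise at low temperatures) is
#' returned with flag `"negative_rate"`, never silently zeroed, so the
#' Arrhenius stage can decide what to exclude.
#'
#' @param series A [kinetic_series()] with at least 2 points at `t > 0` and
#'   all `p_uncut > 0`.
#' @param method `"origin"` (through-origin, default) or `"free"`.
#' @return An object of class `kinetic_fit` with fields `temperature_c`,
#'   `temperature_kelvin`, `k` (cuts s^-1 nucleotide^-1), `k_stderr`,
#'   `r_squared`, `n_points`, `flag`, `method`.
#' @examples
#' s <- kinetic_series(120, c(3600, 7200, 14400), exp(-1e-5 * c(3600, 7200, 14400)))
#' fit_rate_constant(s)$k # exactly 1e-5
#' @export
fit_rate_constant <- function(series, method = c("origin", "free")) {
  stopifnot(inherits(series, "kinetic_series"))
  method <- match.arg(method)
  d <- series$points
  if (any(d$p_uncut <= 0))
    stop("all p_uncut values must be strictly positive", call. = FALSE)
  if (sum(d$time_s > 0) < 2L)
    stop("need at least 2 points with t > 0 to fit a rate", call. = FALSE)
  y <- -log(d$p_uncut)
  t <- d$time_s
  if (method == "origin") {
    fit <- stats::lm(y ~ 0 + t)
    k <- unname(stats::coef(fit)[["t"]])
    se <- .lm_summary(fit)$coefficients["t", "Std. Error"]
    # R^2 against the zero line, the model's forced baseline
    r2 <- if (sum(y^2) > 0) 1 - sum(stats::resid(fit)^2) / sum(y^2) else 1
  } else {
    fit <- stats::lm(y ~ t)
    k <- unname(stats::coef(fit)[["t"]])
    se <- .lm_summary(fit)$coefficients["t", "Std. Error"]
    r2 <- .lm_summary(fit)$r.squared
  }
  structure(
    list(temperature_c = series$temperature_c,
         temperature_kelvin = series$temperature_c + 273.15,
         k = k, k_stderr = se, r_squared = r2,
         n_points = nrow(d),
         flag = if (k < 0) "negative_rate" else "ok",
         method = method),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "k(%g degC) = %.4g cuts/s/nt (se %.2g, R^2 %.3f, n = %d%s)\n",
    x$temperature_c, x$k, x$k_stderr, x$r_squared, x$n_points,
    if (x$flag != "ok") paste0(", flag: ", x$flag) else ""))
  invisible(x)
}


#' Group copy-number measurements into per-temperature kinetic series
#'
#' For each capsule at each time point, replicate copy numbers are combined
#' by geometric mean per amplicon (qPCR error is multiplicative) before the
#' survival probability is computed; each capsule-time combination then
#' contributes one point to its temperature's series.
#'
#' @param measurements A data frame with columns `temperature_c`, `time_s`,
#'   `capsule_id`, `n_long`, `n_short` (one row per qPCR replicate), e.g.
#'   from [simulate_study()] or [read_measurements()].
#' @param pair The [amplicon_pair()] the copy numbers refer to.
#' @return A list of [kinetic_series()], one per temperature, ascending.
#' @export
build_series <- function(measurements, pair = amplicon_pair()) {
  agg <- aggregate_measurements(measurements, pair)
  temps <- sort(unique(agg$temperature_c))
  lapply(temps, function(tc) {
    d <- agg[agg$temperature_c == tc, , drop = FALSE]
    kinetic_series(tc, d$time_s, d$p_uncut, d$capsule_id)
  })
}

#' Per-capsule geometric-mean copy numbers and survival estimates
#'
#' The aggregation step shared by [build_series()] and [estimate_p_uncut()]:
#' replicate copy numbers are combined by geometric mean per amplicon within
#' each temperature/time/capsule cell, then the survival probability is
#' estimated from the aggregated pair. Survival is computed in log domain so
#' heavily degraded long-amplicon values near the double-precision floor do
#' not underflow the ratio.
#'
#' @inheritParams build_series
#' @return A data frame with columns `temperature_c`, `time_s`,
#'   `capsule_id`, `n_long_gm`, `n_short_gm`, `p_uncut`.
#' @export
aggregate_measurements <- function(measurements, pair = amplicon_pair()) {
  stopifnot(inherits(pair, "amplicon_pair"))
  req <- c("temperature_c", "time_s", "capsule_id", "n_long", "n_short")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("measurements lack required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(measurements) == 0L)
    stop("measurements table is empty", call. = FALSE)
  if (any(measurements$n_long <= 0) || any(measurements$n_short <= 0))
    stop("copy numbers must be strictly positive", call. = FALSE)
  agg <- stats::aggregate(
    cbind(ln1 = log(measurements$n_long), ln2 = log(measurements$n_short)),
    by = list(temperature_c = measurements$temperature_c,
              time_s = measurements$time_s,
              capsule_id = measurements$capsule_id),
    FUN = mean
  )
  data.frame(temperature_c = agg$temperature_c, time_s = agg$time_s,
             capsule_id = agg$capsule_id,
             n_long_gm = exp(agg$ln1), n_short_gm = exp(agg$ln2),
             p_uncut = exp((agg$ln1 - agg$ln2) / (pair$L1 - pair$L2)))
}
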