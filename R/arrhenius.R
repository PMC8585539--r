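# Arrhenius regression over per-temperature rate constants and extrapolation
# to storage temperature: k(T) = A exp(-Ea / (R T)), linear as
# ln k = ln A - (Ea/R) (1/T).

#' Gas constant, J mol^-1 K^-1
#' @export
GAS_CONSTANT <- 8.314

.KELVIN_OFFSET <- 273.15

#' Construct an Arrhenius model directly
#'
#' Mostly used for anchored models (see [arrhenius_from_anchor()]) and
#' internally by [fit_arrhenius()].
#'
#' @param activation_energy Activation energy Ea in J mol^-1.
#' @param ln_prefactor Natural log of the pre-exponential factor A (A in
#'   s^-1 units).
#' @param r_squared,n_temperatures Fit diagnostics (NA for constructed
#'   models).
#' @param temperature_range_kelvin Range of temperatures the model was
#'   fitted on; queries outside it are marked as extrapolated.
#' @return An object of class `arrhenius_model`.
#' @export
arrhenius_model <- function(activation_energy, ln_prefactor,
                            r_squared = NA_real_,
                            n_temperatures = NA_integer_,
                            temperature_range_kelvin = c(NA_real_, NA_real_)) {
  structure(
    list(activation_energy = activation_energy,
         ln_prefactor = ln_prefactor,
         r_squared = r_squared,
         n_temperatures = n_temperatures,
         temperature_range_kelvin = temperature_range_kelvin,
         gas_constant = GAS_CONSTANT),
    class = "arrhenius_model"
  )
}

#' Arrhenius model anchored at a known rate
#'
#' Builds the model with a given activation energy that passes through a
#' known rate at a reference temperature:
#' `ln A = ln k_ref + Ea / (R T_ref)`.
#'
#' @param activation_energy Ea in J mol^-1.
#' @param k_ref Rate constant at the reference temperature
#'   (cuts s^-1 nucleotide^-1).
#' @param temperature_ref_c Reference temperature in degrees Celsius.
#' @return An `arrhenius_model`.
#' @examples
#' m <- arrhenius_from_anchor(197e3, 3.82e-15, 25)
#' rate_at(m, 25) # 3.82e-15 by construction
#' @export
arrhenius_from_anchor <- function(activation_energy, k_ref,
                                  temperature_ref_c) {
  if (k_ref <= 0) stop("k_ref must be positive", call. = FALSE)
  Tref <- temperature_ref_c + .KELVIN_OFFSET
  arrhenius_model(activation_energy,
                  log(k_ref) + activation_energy / (GAS_CONSTANT * Tref))
}

#' Fit the Arrhenius law to per-temperature rate constants
#'
#' Ordinary least squares of `ln k` on `1/T` (T in kelvin):
#' `Ea = -slope * R`, `ln A = intercept`. Unweighted by default; set
#' `weighted = TRUE` to weight each point by `(k / k_stderr)^2`, the inverse
#' variance of `ln k` by the delta method. Fits with non-positive rate
#' estimates (flagged upstream) are excluded with a warning.
#'
#' @param fits A list of [fit_rate_constant()] results (class `kinetic_fit`).
#' @param weighted Logical; use inverse-variance weights on `ln k`.
#' @return An `arrhenius_model` carrying the fitted temperature range.
#' @export
fit_arrhenius <- function(fits, weighted = FALSE) {
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  if (!length(fits) || !all(vapply(fits, inherits, TRUE, "kinetic_fit")))
    stop("fits must be a list of kinetic_fit objects", call. = FALSE)
  k <- vapply(fits, `[[`, 0, "k")
  Tk <- vapply(fits, `[[`, 0, "temperature_kelvin")
  se <- vapply(fits, `[[`, 0, "k_stderr")
  usable <- k > 0
  if (any(!usable))
    warning(sum(!usable), " non-positive rate estimate(s) excluded from the ",
            "Arrhenius fit (temperatures: ",
            paste(Tk[!usable] - .KELVIN_OFFSET, collapse = ", "), " degC)",
            call. = FALSE)
  k <- k[usable]; Tk <- Tk[usable]; se <- se[usable]
  if (length(k) < 2L)
    stop("need at least 2 temperatures with positive rates", call. = FALSE)
  x <- 1 / Tk
  y <- log(k)
  w <- if (weighted) (k / se)^2 else NULL
  fit <- if (weighted) stats::lm(y ~ x, weights = w) else stats::lm(y ~ x)
  arrhenius_model(
    activation_energy = -unname(stats::coef(fit)[["x"]]) * GAS_CONSTANT,
    ln_prefactor = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = .lm_summary(fit)$r.squared,
    n_temperatures = length(k),
    temperature_range_kelvin = range(Tk)
  )
}

#' Evaluate the Arrhenius rate at a temperature
#'
#' Returns `exp(ln A - Ea / (R T))`. Extrapolation outside the fitted
#' temperature span is permitted -- that extrapolation is the entire point
#' of accelerated aging -- but the result carries an `extrapolated`
#' attribute so reports can label it.
#'
#' @param model An `arrhenius_model`.
#' @param temperature_c Temperature in degrees Celsius (> -273.15).
#' @return Rate constant in cuts s^-1 nucleotide^-1, with logical attribute
#'   `extrapolated`.
#' @export
rate_at <- function(model, temperature_c) {
  stopifnot(inherits(model, "arrhenius_model"))
  if (any(temperature_c <= -.KELVIN_OFFSET))
    stop("temperature must be above absolute zero", call. = FALSE)
  Tk <- temperature_c + .KELVIN_OFFSET
  k <- exp(model$ln_prefactor -
             model$activation_energy / (model$gas_constant * Tk))
  rng <- model$temperature_range_kelvin
  extrap <- if (all(is.finite(rng))) Tk < rng[1] | Tk > rng[2] else
    rep(NA, length(Tk))
  attr(k, "extrapolated") <- extrap
  k
}

#' @export
print.arrhenius_model <- function(x, ...) {
  cat(sprintf("Arrhenius model: Ea = %.1f kJ/mol, ln A = %.3f (A = %.3g /s)\n",
              x$activation_energy / 1000, x$ln_prefactor,
              exp(x$ln_prefactor)))
  if (is.finite(x$r_squared))
    cat(sprintf("  fitted on %d temperatures (%.0f-%.0f degC), R^2 = %.4f\n",
                x$n_temperatures,
                x$temperature_range_kelvin[1] - .KELVIN_OFFSET,
                x$temperature_range_kelvin[2] - .KELVIN_OFFSET,
                x$r_squared))
  invisible(x)
}

#' Summarise an Arrhenius model as a report list
#'
#' @param model An `arrhenius_model`.
#' @param temperatures_c Temperatures at which to tabulate rates.
#' @return A list ready for JSON serialisation:
#'   `activation_energy_kj_mol`, `ln_prefactor`, `r_squared`, `rates`.
#' @export
arrhenius_report <- function(model, temperatures_c = numeric(0)) {
  stopifnot(inherits(model, "arrhenius_model"))
  rates <- lapply(temperatures_c, function(tc) {
    k <- rate_at(model, tc)
    list(temperature_c = tc, k = as.numeric(k),
         extrapolated = isTRUE(attr(k, "extrapolated")))
  })
  list(activation_energy_kj_mol = model$activation_energy / 1000,
       ln_prefactor = model$ln_prefactor,
       r_squared = model$r_squared,
       n_temperatures = model$n_temperatures,
       rates = rates)
}
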