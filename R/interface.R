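# Tabular I/O and the end-to-end analysis: measurements CSV -> per-capsule
# survival estimates -> per-temperature rate fits -> Arrhenius model ->
# longevity report at a storage temperature.

.TIME_FACTORS <- c(s = 1, min = 60, h = 3600)

#' Read an accelerated-aging measurements table
#'
#' Expects the CSV schema `temperature_c, time_value, time_unit, capsule_id,
#' replicate_id, n_long, n_short` with `time_unit` one of `s`, `min`, `h`.
#' Unknown columns are ignored with a warning; malformed rows produce errors
#' naming the offending line numbers. Times are converted to seconds in a
#' `time_s` column.
#'
#' @param path Path to a CSV file.
#' @return A data frame in the schema [build_series()] consumes.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("temperature_c", "time_value", "time_unit", "capsule_id",
           "replicate_id", "n_long", "n_short")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("measurements CSV lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), req)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    df <- df[req]
  }
  if (nrow(df) == 0L)
    stop("measurements CSV contains no data rows: ", path, call. = FALSE)
  # +1 for header: report line numbers as they appear in the file
  bad_unit <- which(!df$time_unit %in% names(.TIME_FACTORS))
  if (length(bad_unit))
    stop("unknown time_unit at line(s) ",
         paste(bad_unit + 1L, collapse = ", "),
         " (expected s, min or h)", call. = FALSE)
  for (col in c("temperature_c", "time_value", "n_long", "n_short")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop("non-numeric ", col, " at line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    df[[col]] <- vals
  }
  neg <- which(df$time_value < 0)
  if (length(neg))
    stop("negative time_value at line(s) ", paste(neg + 1L, collapse = ", "),
         call. = FALSE)
  df$time_s <- df$time_value * .TIME_FACTORS[df$time_unit]
  df
}

#' Write a measurements table to CSV
#'
#' @param measurements A data frame such as [simulate_study()] returns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  cols <- c("temperature_c", "time_value", "time_unit", "capsule_id",
            "replicate_id", "n_long", "n_short")
  utils::write.csv(measurements[cols], path, row.names = FALSE)
  invisible(path)
}

#' Per-capsule survival estimates as a table
#'
#' Convenience view of the estimation stage: geometric-mean copy numbers per
#' capsule and time point, the survival estimate `p_uncut`, and its quality
#' flag.
#'
#' @param measurements Measurements data frame (see [read_measurements()]).
#' @param pair An [amplicon_pair()].
#' @return A data frame with one row per temperature/time/capsule.
#' @export
estimate_p_uncut <- function(measurements, pair = amplicon_pair()) {
  out <- aggregate_measurements(measurements, pair)
  out <- out[order(out$temperature_c, out$time_s, out$capsule_id), ]
  out$flag <- ifelse(out$p_uncut > 1, "p_above_one", "ok")
  rownames(out) <- NULL
  out
}

#' Run the full degradation analysis
#'
#' Measurements to longevity in one call: per-capsule survival estimation,
#' per-temperature rate fits, Arrhenius regression, extrapolation to the
#' storage temperature and a longevity report there. Warnings encountered on
#' the way (survival estimates above 1, rate fits excluded from the
#' Arrhenius stage) are collected in the report.
#'
#' @param measurements A measurements data frame, or a path to a CSV in the
#'   [read_measurements()] schema.
#' @param pair An [amplicon_pair()].
#' @param storage_temperature_c Temperature to extrapolate to (default 25).
#' @param fit_method Per-temperature fit: `"origin"` or `"free"`, see
#'   [fit_rate_constant()].
#' @param weighted_arrhenius Weight the Arrhenius fit by inverse variance of
#'   `ln k`; see [fit_arrhenius()].
#' @param expected_copies Optional expected genome copies per aliquot; when
#'   supplied, a per-measurement recovery table is included.
#' @param ... Passed to [longevity_report()] (fragment length, copy counts,
#'   target mean length, year convention).
#' @return An object of class `degradation_report`: list with
#'   `kinetic_fits` (data frame), `arrhenius` (model), `storage` (rate and
#'   temperature), `longevity`, optional `recovery`, and `warnings`.
#' @export
run_full_analysis <- function(measurements, pair = amplicon_pair(),
                              storage_temperature_c = 25,
                              fit_method = c("origin", "free"),
                              weighted_arrhenius = FALSE,
                              expected_copies = NULL, ...) {
  fit_method <- match.arg(fit_method)
  if (is.character(measurements) && length(measurements) == 1L)
    measurements <- read_measurements(measurements)
  warnings <- character(0)

  series <- build_series(measurements, pair)
  n_above <- sum(vapply(series, function(s) sum(s$points$p_uncut > 1), 0L))
  if (n_above > 0)
    warnings <- c(warnings, sprintf(
      "%d survival estimate(s) above 1 retained unclamped", n_above))

  fits <- lapply(series, fit_rate_constant, method = fit_method)
  n_neg <- sum(vapply(fits, function(f) f$flag != "ok", FALSE))
  if (n_neg > 0)
    warnings <- c(warnings, sprintf(
      "%d non-positive rate fit(s) excluded from the Arrhenius stage", n_neg))

  model <- withCallingHandlers(
    fit_arrhenius(fits, weighted = weighted_arrhenius),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  k_store <- rate_at(model, storage_temperature_c)
  extrap <- isTRUE(attr(k_store, "extrapolated"))
  if (extrap)
    warnings <- c(warnings, sprintf(
      "rate at %g degC is extrapolated outside the fitted %g-%g degC range",
      storage_temperature_c,
      model$temperature_range_kelvin[1] - 273.15,
      model$temperature_range_kelvin[2] - 273.15))

  report <- list(
    schema_version = "1.0",
    kinetic_fits = do.call(rbind, lapply(fits, function(f) {
      data.frame(temperature_c = f$temperature_c, k = f$k,
                 k_stderr = f$k_stderr, r_squared = f$r_squared,
                 n_points = f$n_points, flag = f$flag)
    })),
    arrhenius = model,
    storage = list(temperature_c = storage_temperature_c,
                   k = as.numeric(k_store), extrapolated = extrap),
    longevity = longevity_report(as.numeric(k_store),
                                 extrapolated = extrap, ...),
    warnings = warnings
  )
  if (!is.null(expected_copies)) {
    est <- estimate_p_uncut(measurements, pair)
    g <- genomic_copies(est$n_long_gm, est$n_short_gm, pair)
    report$recovery <- data.frame(
      temperature_c = est$temperature_c, time_s = est$time_s,
      capsule_id = est$capsule_id,
      recovery = recovery_fraction(g, expected_copies))
  }
  class(report) <- "degradation_report"
  report
}

#' @export
print.degradation_report <- function(x, ...) {
  cat("Degradation analysis\n====================\n")
  cat("Per-temperature rate constants:\n")
  print(x$kinetic_fits, row.names = FALSE)
  print(x$arrhenius)
  cat(sprintf("Rate at %g degC: %.3g cuts/s/nt%s\n",
              x$storage$temperature_c, x$storage$k,
              if (x$storage$extrapolated) " (extrapolated)" else ""))
  print(x$longevity)
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Serialise a report to JSON
#'
#' Floats keep full double precision (15 significant digits) so reports
#' round-trip losslessly; two runs with identical inputs and seed produce
#' byte-identical files.
#'
#' @param report A `degradation_report` (or any serialisable list).
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_report <- function(report, path = NULL) {
  if (inherits(report, "degradation_report")) {
    report <- list(
      schema_version = report$schema_version,
      kinetic_fits = report$kinetic_fits,
      arrhenius = arrhenius_report(report$arrhenius),
      storage = report$storage,
      longevity = unclass(report$longevity),
      warnings = report$warnings,
      recovery = report$recovery
    )
  }
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 15,
                           null = "null", na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Recover Arrhenius parameters over replicated synthetic studies
#'
#' Runs the full estimation pipeline on `n_replicates` independently seeded
#' synthetic studies generated under a common truth, and returns the
#' recovered activation energy and storage-temperature rate per replicate.
#' This is the package's parameter-recovery harness: with the default truth
#' and design it quantifies how well the pipeline re-finds the generating
#' Arrhenius law under realistic measurement noise.
#'
#' @param n_replicates Number of studies.
#' @param truth_args List of arguments to [simulation_truth()] other than
#'   `seed` (defaults used when omitted).
#' @param design A [study_design()].
#' @param pair An [amplicon_pair()].
#' @param seed Master seed; replicate seeds are derived deterministically.
#' @param storage_temperature_c Temperature for the recovered rate.
#' @return A data frame with columns `replicate`, `seed`, `activation_energy`
#'   (J/mol), `k_storage`.
#' @export
recover_parameters <- function(n_replicates = 100, truth_args = list(),
                               design = default_study_design(),
                               pair = amplicon_pair(), seed = 1,
                               storage_temperature_c = 25) {
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, n_replicates))
  rows <- lapply(seq_len(n_replicates), function(i) {
    truth <- do.call(simulation_truth, c(truth_args, list(seed = seeds[i])))
    study <- simulate_study(design, truth, pair)
    fits <- lapply(build_series(study, pair), fit_rate_constant)
    model <- fit_arrhenius(fits)
    data.frame(replicate = i, seed = seeds[i],
               activation_energy = model$activation_energy,
               k_storage = as.numeric(rate_at(model, storage_temperature_c)))
  })
  do.call(rbind, rows)
}
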