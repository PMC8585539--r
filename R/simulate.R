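# Seeded generator of synthetic accelerated-aging studies with the
# statistical structure the estimation pipeline assumes: per-position
# survival e^(-kt) with Arrhenius-dependent k, amplifiability exponents
# L - 1, and mean-preserving multiplicative lognormal measurement noise on
# copy numbers.

#' Accelerated-aging study design
#'
#' Describes the layout of a heat-stress study: which temperatures, how many
#' time points per temperature, how many capsules per time point and how
#' many qPCR replicates per capsule. [default_study_design()] reproduces the
#' canonical five-temperature layout (47 capsules in total).
#'
#' @param temperatures_c Temperatures in degrees Celsius.
#' @param n_time_points Number of time points per temperature (>= 2 each).
#' @param capsules_per_point Capsules retrieved per time point, per
#'   temperature (recycled if length 1).
#' @param qpcr_replicates qPCR determinations per capsule.
#' @param time_grids Optional list of explicit time grids (seconds), one per
#'   temperature; if `NULL`, grids are placed automatically at simulation
#'   time so the long amplicon decays through a measurable range (see
#'   [default_time_grid()]).
#' @return An object of class `study_design`.
#' @export
study_design <- function(temperatures_c, n_time_points, capsules_per_point,
                         qpcr_replicates = 3, time_grids = NULL) {
  nT <- length(temperatures_c)
  if (length(n_time_points) != nT)
    stop("n_time_points must match temperatures_c in length", call. = FALSE)
  capsules_per_point <- rep_len(capsules_per_point, nT)
  if (any(n_time_points < 2))
    stop("every temperature needs at least 2 time points", call. = FALSE)
  if (any(capsules_per_point < 1) || qpcr_replicates < 1)
    stop("capsule and replicate counts must be >= 1", call. = FALSE)
  if (!is.null(time_grids)) {
    if (length(time_grids) != nT ||
        !all(lengths(time_grids) == n_time_points))
      stop("time_grids must supply one grid per temperature, matching ",
           "n_time_points", call. = FALSE)
  }
  structure(
    list(temperatures_c = temperatures_c,
         n_time_points = n_time_points,
         capsules_per_point = capsules_per_point,
         qpcr_replicates = as.integer(qpcr_replicates),
         time_grids = time_grids),
    class = "study_design"
  )
}

#' Canonical five-temperature study design
#'
#' 100-140 degC in 10-degree steps; 4, 3, 3, 4 and 3 time points and 3, 3,
#' 3, 2 and 3 capsules per point respectively, with triplicate qPCR: 47
#' capsules and 141 qPCR records per amplicon in total.
#'
#' @return A [study_design()].
#' @export
default_study_design <- function() {
  study_design(
    temperatures_c = c(100, 110, 120, 130, 140),
    n_time_points = c(4, 3, 3, 4, 3),
    capsules_per_point = c(3, 3, 3, 2, 3),
    qpcr_replicates = 3
  )
}

#' Total capsules in a design
#' @param design A [study_design()].
#' @return Integer capsule count (sum over temperatures of time points times
#'   capsules per point).
#' @export
n_capsules <- function(design) {
  stopifnot(inherits(design, "study_design"))
  sum(design$n_time_points * design$capsules_per_point)
}

#' Generating truth for a simulated study
#'
#' The ground-truth degradation model: an Arrhenius law specified by its
#' activation energy and an anchor rate at a reference temperature, the
#' genome copies loaded per qPCR aliquot, and the measurement noise level.
#' Defaults: Ea = 197 kJ/mol anchored at k(25 degC) = 3.82e-15 cuts/s/nt;
#' 2530 genome copies per aliquot (8.35 ng of human genomic DNA at ~3.3 pg
#' per haploid genome); lognormal noise with CV 0.15.
#'
#' @param activation_energy Ea in J mol^-1.
#' @param k_reference Anchor rate at `reference_temperature_c`,
#'   cuts s^-1 nucleotide^-1.
#' @param reference_temperature_c Anchor temperature, degrees Celsius.
#' @param genome_copies_per_aliquot Template copies per qPCR reaction.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (>= 0; 0 disables noise).
#' @param seed Integer seed; mandatory for every stochastic run.
#' @return An object of class `simulation_truth` (including the implied
#'   `ln_prefactor` and an `arrhenius_model`).
#' @export
simulation_truth <- function(activation_energy = 197e3,
                             k_reference = 3.82e-15,
                             reference_temperature_c = 25,
                             genome_copies_per_aliquot = 2530,
                             noise_cv = 0.15,
                             seed) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (genome_copies_per_aliquot <= 0)
    stop("genome_copies_per_aliquot must be positive", call. = FALSE)
  model <- arrhenius_from_anchor(activation_energy, k_reference,
                                 reference_temperature_c)
  structure(
    list(activation_energy = activation_energy,
         k_reference = k_reference,
         reference_temperature_c = reference_temperature_c,
         ln_prefactor = model$ln_prefactor,
         model = model,
         genome_copies_per_aliquot = genome_copies_per_aliquot,
         noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = "simulation_truth"
  )
}

# lognormal multiplier with mean exactly 1: sdlog^2 = ln(1 + cv^2),
# meanlog = -sdlog^2 / 2
.noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate one noisy pair of amplicon copy numbers
#'
#' Forward model: expected copies `N0 * e^(-k t (L_i - 1))` for each
#' amplicon, then an independent mean-preserving lognormal factor per
#' measurement. With `noise_cv = 0` the expectations are returned exactly.
#' Draws come from R's current RNG stream; seed with [withr::with_seed()]
#' (as [simulate_study()] does) for reproducibility.
#'
#' @param N0 Genome copies in the reaction (> 0).
#' @param k Per-nucleotide cut rate (>= 0).
#' @param t Elapsed time in seconds (>= 0).
#' @param pair An [amplicon_pair()].
#' @param noise_cv Lognormal noise CV (>= 0).
#' @return Named numeric vector `c(N1 = ..., N2 = ...)`.
#' @export
simulate_copy_pair <- function(N0, k, t, pair = amplicon_pair(),
                               noise_cv = 0) {
  stopifnot(inherits(pair, "amplicon_pair"))
  if (N0 <= 0 || k < 0 || t < 0 || noise_cv < 0)
    stop("need N0 > 0, k >= 0, t >= 0, noise_cv >= 0", call. = FALSE)
  expected <- N0 * exp(-k * t * (c(pair$L1, pair$L2) - 1))
  out <- expected * .noise_factor(2L, noise_cv)
  names(out) <- c("N1", "N2")
  out
}

#' Default time grid for one temperature
#'
#' Places `n_points` times geometrically between the moments at which the
#' long amplicon's survival reaches `survival_range[1]` and
#' `survival_range[2]` (defaults 80% down to 1%). This mirrors how heating
#' durations are chosen in practice: long enough that the long amplicon
#' decays measurably, short enough that it still amplifies.
#'
#' @param k Per-nucleotide cut rate at the temperature (> 0).
#' @param n_points Number of time points.
#' @param pair An [amplicon_pair()].
#' @param survival_range Survival of the long amplicon at the first and last
#'   time point.
#' @return Times in seconds, increasing.
#' @export
default_time_grid <- function(k, n_points, pair = amplicon_pair(),
                              survival_range = c(0.8, 0.01)) {
  if (k <= 0) stop("k must be positive to place a time grid", call. = FALSE)
  span <- -log(survival_range) / (k * (pair$L1 - 1))
  exp(seq(log(span[1]), log(span[2]), length.out = n_points))
}

#' Simulate a full accelerated-aging study
#'
#' One record per (temperature, time point, capsule, qPCR replicate): the
#' per-temperature rate comes from the truth's Arrhenius law, expected copy
#' numbers from the random-breakage forward model, and each replicate
#' measurement gets independent lognormal noise. The result uses the same
#' schema [build_series()] and [read_measurements()] consume, and carries
#' the truth as an attribute for recovery tests.
#'
#' @param design A [study_design()].
#' @param truth A [simulation_truth()] (its `seed` drives all randomness;
#'   the global RNG state is left untouched).
#' @param pair An [amplicon_pair()].
#' @return A data frame with columns `temperature_c`, `time_value`,
#'   `time_unit` (always `"s"`), `time_s`, `capsule_id`, `replicate_id`,
#'   `n_long`, `n_short`, and attribute `"truth"`.
#' @export
simulate_study <- function(design = default_study_design(),
                           truth, pair = amplicon_pair()) {
  stopifnot(inherits(design, "study_design"),
            inherits(truth, "simulation_truth"),
            inherits(pair, "amplicon_pair"))
  withr::with_seed(truth$seed, {
    rows <- vector("list", length(design$temperatures_c))
    for (i in seq_along(design$temperatures_c)) {
      tc <- design$temperatures_c[i]
      k <- as.numeric(rate_at(truth$model, tc))
      times <- if (!is.null(design$time_grids)) design$time_grids[[i]] else
        default_time_grid(k, design$n_time_points[i], pair)
      grid <- expand.grid(
        replicate_id = seq_len(design$qpcr_replicates),
        capsule = seq_len(design$capsules_per_point[i]),
        time_idx = seq_along(times)
      )
      t_s <- times[grid$time_idx]
      expected1 <- truth$genome_copies_per_aliquot *
        exp(-k * t_s * (pair$L1 - 1))
      expected2 <- truth$genome_copies_per_aliquot *
        exp(-k * t_s * (pair$L2 - 1))
      n <- nrow(grid)
      rows[[i]] <- data.frame(
        temperature_c = tc,
        time_value = t_s,
        time_unit = "s",
        time_s = t_s,
        capsule_id = sprintf("T%g_t%d_c%d", tc, grid$time_idx, grid$capsule),
        replicate_id = grid$replicate_id,
        n_long = expected1 * .noise_factor(n, truth$noise_cv),
        n_short = expected2 * .noise_factor(n, truth$noise_cv)
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Monte-Carlo fragment survival
#'
#' Direct per-fragment simulation used as a brute-force oracle for the
#' longevity projections: each of the `length` positions of each fragment
#' is cut independently with probability `1 - e^(-k t)`, and a fragment is
#' intact iff no position is cut, i.e. with probability `e^(-k t length)`.
#' Draws from the current RNG stream; seed with [withr::with_seed()].
#'
#' @param n_fragments Number of fragments to simulate (> 0).
#' @param length Fragment length in nucleotides (>= 1).
#' @param k Per-nucleotide cut rate (>= 0).
#' @param t Elapsed time in seconds (>= 0).
#' @return Logical vector: `TRUE` where the fragment is intact.
#' @export
simulate_fragment_population <- function(n_fragments, length, k, t) {
  if (n_fragments <= 0 || length < 1 || k < 0 || t < 0)
    stop("need n_fragments > 0, length >= 1, k >= 0, t >= 0", call. = FALSE)
  stats::rbinom(n_fragments, 1L, exp(-k * t * length)) == 1L
}
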