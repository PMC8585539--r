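# Longevity arithmetic from an extrapolated cut rate.
#
# Convention: k is defined per nucleotide, so a fragment of L nucleotides
# accumulates cuts at rate k*L and survives intact with probability
# e^(-k L t). (Counting L-1 internal bonds instead changes the 150-nt
# half-life from ~38,300 to ~38,600 years; the per-nucleotide convention is
# used throughout the projections, while amplifiability in the breakage
# model keeps its L-1 exponent.)

#' Seconds in a Julian year
#'
#' Fixed conversion used wherever times are reported in years. Alternative
#' conventions change reported values by < 0.1%.
#' @export
SECONDS_PER_YEAR <- 3.1557e7

#' Half-life of an intact DNA fragment
#'
#' A fragment of `L` nucleotides survives while none of its positions is
#' cut; survival is `e^(-k L t)`, so the half-life is `ln 2 / (k L)`.
#'
#' @param k Per-nucleotide cut rate, cuts s^-1 nucleotide^-1 (> 0).
#' @param L Fragment length in nucleotides (>= 1).
#' @param seconds_per_year Year convention; see [SECONDS_PER_YEAR].
#' @return Half-life in years.
#' @examples
#' fragment_half_life(3.82e-15, 150) # ~38,000 years
#' @export
fragment_half_life <- function(k, L, seconds_per_year = SECONDS_PER_YEAR) {
  if (any(k <= 0)) stop("k must be positive", call. = FALSE)
  if (any(L < 1)) stop("fragment length must be >= 1", call. = FALSE)
  log(2) / (k * L) / seconds_per_year
}

#' Expected number of cuts over a stated duration
#'
#' Linear cut budget: `k * duration_in_seconds * n_nucleotides`.
#'
#' @param k Per-nucleotide cut rate (> 0).
#' @param duration_years Duration in years (>= 0).
#' @param n_nucleotides Number of nucleotide positions tracked (> 0).
#' @inheritParams fragment_half_life
#' @return Expected (fractional) cut count.
#' @examples
#' expected_cuts(3.82e-15, 100, 1e5) # ~1.2 cuts per century per 100 kb
#' @export
expected_cuts <- function(k, duration_years, n_nucleotides,
                          seconds_per_year = SECONDS_PER_YEAR) {
  if (any(k <= 0) || any(n_nucleotides <= 0) || any(duration_years < 0))
    stop("k and n_nucleotides must be positive, duration non-negative",
         call. = FALSE)
  k * duration_years * seconds_per_year * n_nucleotides
}

#' Time until the mean fragment length falls to a target
#'
#' Under random scission the mean fragment length is `1 / P_cut =
#' 1 / (1 - e^(-k t))`; solving for the time at which it reaches
#' `target_length` gives `t = -ln(1 - 1/target_length) / k`.
#'
#' @param k Per-nucleotide cut rate (> 0).
#' @param target_length Target mean fragment length in nucleotides (> 1).
#' @inheritParams fragment_half_life
#' @return Time in years.
#' @export
time_to_mean_length <- function(k, target_length,
                                seconds_per_year = SECONDS_PER_YEAR) {
  if (any(k <= 0)) stop("k must be positive", call. = FALSE)
  if (any(target_length <= 1))
    stop("target_length must exceed 1 nucleotide", call. = FALSE)
  -log(1 - 1 / target_length) / k / seconds_per_year
}

#' Time until intact copies decay to a minimum retrievable count
#'
#' First-order decay of intact `L`-nt copies: the time at which
#' `copies_start * e^(-k L t)` reaches `copies_min`, i.e.
#' `ln(copies_start/copies_min) / (k L)`. With a 2:1 start:minimum ratio this
#' is exactly the fragment half-life.
#'
#' @param k Per-nucleotide cut rate (> 0).
#' @param L Copy length in nucleotides (>= 1).
#' @param copies_start Starting copy count (> `copies_min`).
#' @param copies_min Minimum copy count needed for faithful retrieval (> 0).
#' @inheritParams fragment_half_life
#' @return Horizon in years.
#' @export
retrieval_horizon <- function(k, L, copies_start, copies_min,
                              seconds_per_year = SECONDS_PER_YEAR) {
  if (any(k <= 0)) stop("k must be positive", call. = FALSE)
  if (any(L < 1)) stop("copy length must be >= 1", call. = FALSE)
  if (any(copies_min <= 0) || any(copies_start <= copies_min))
    stop("need copies_start > copies_min > 0", call. = FALSE)
  log(copies_start / copies_min) / (k * L) / seconds_per_year
}

#' Assemble a longevity report for a storage scenario
#'
#' Bundles the longevity projections for one cut rate: half-life of a
#' fragment, cut budget over a stated interval, time to a target mean
#' fragment length, and the minimum-copy retrieval horizon.
#'
#' @param k Per-nucleotide cut rate (> 0), typically [rate_at()] the storage
#'   temperature.
#' @param fragment_length Fragment length for the half-life and horizon
#'   (default 150 nt, the customary comparison size).
#' @param cut_budget_years,cut_budget_nucleotides Interval and nucleotide
#'   count for the cut budget (defaults: one century, 1e5 nt).
#' @param copies_start,copies_min Copy counts for the retrieval horizon
#'   (defaults 20 and 10).
#' @param target_length Target mean fragment length (default 25 nt, the
#'   practical lower limit for sequencing degraded DNA).
#' @param extrapolated Logical marker carried into the report when `k` came
#'   from an Arrhenius extrapolation outside the fitted range.
#' @inheritParams fragment_half_life
#' @return An object of class `longevity_report`.
#' @export
longevity_report <- function(k, fragment_length = 150,
                             cut_budget_years = 100,
                             cut_budget_nucleotides = 1e5,
                             copies_start = 20, copies_min = 10,
                             target_length = 25,
                             extrapolated = NA,
                             seconds_per_year = SECONDS_PER_YEAR) {
  structure(
    list(k = as.numeric(k),
         fragment_length = fragment_length,
         half_life_years = fragment_half_life(k, fragment_length,
                                              seconds_per_year),
         cuts_per_interval = expected_cuts(k, cut_budget_years,
                                           cut_budget_nucleotides,
                                           seconds_per_year),
         cut_budget_years = cut_budget_years,
         cut_budget_nucleotides = cut_budget_nucleotides,
         t_to_mean_length_years = time_to_mean_length(k, target_length,
                                                      seconds_per_year),
         target_length = target_length,
         retrieval_horizon_years = retrieval_horizon(k, fragment_length,
                                                     copies_start, copies_min,
                                                     seconds_per_year),
         copies_start = copies_start, copies_min = copies_min,
         extrapolated = extrapolated,
         seconds_per_year = seconds_per_year),
    class = "longevity_report"
  )
}

#' @export
print.longevity_report <- function(x, ...) {
  cat(sprintf("Longevity at k = %.3g cuts/s/nt%s\n", x$k,
              if (isTRUE(x$extrapolated)) " (extrapolated rate)" else ""))
  cat(sprintf("  half-life of a %d-nt fragment:   %s years\n",
              x$fragment_length, signif(x$half_life_years, 2)))
  cat(sprintf("  expected cuts per %g years per %g nt: %.2f\n",
              x$cut_budget_years, x$cut_budget_nucleotides,
              x$cuts_per_interval))
  cat(sprintf("  time to mean length %d nt:       %s years\n",
              x$target_length, signif(x$t_to_mean_length_years, 2)))
  cat(sprintf("  %g -> %g copies of %d nt:         %s years\n",
              x$copies_start, x$copies_min, x$fragment_length,
              signif(x$retrieval_horizon_years, 2)))
  invisible(x)
}
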