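# Random-breakage forward model and two-amplicon estimators.
#
# Under random chain scission, each internucleotide position survives
# independently with probability p = P_uncut. An L-bp amplicon amplifies only
# if all of its L - 1 internal positions are intact, so the expected number of
# amplifiable copies is N0 * p^(L - 1). Comparing two amplicons of different
# lengths cancels the (unknown) recovery and yields p directly.

#' Define a pair of qPCR amplicons
#'
#' The two-amplicon degradation estimator compares the amplifiable copy
#' numbers of a long and a short amplicon targeting the same locus. The
#' default lengths (1064 bp and 93 bp) correspond to the TAF1L amplicons used
#' throughout the package examples.
#'
#' @param L1 Length of the long amplicon in base pairs (integer, > `L2`).
#' @param L2 Length of the short amplicon in base pairs (integer, > 1).
#' @param name_long,name_short Optional display names.
#'
#' @return An object of class `amplicon_pair`.
#' @examples
#' amplicon_pair(1064, 93)
#' @export
amplicon_pair <- function(L1 = 1064, L2 = 93,
                          name_long = paste0("amp", L1),
                          name_short = paste0("amp", L2)) {
  if (!is.numeric(L1) || !is.numeric(L2) || length(L1) != 1L || length(L2) != 1L)
    stop("amplicon lengths must be single numbers", call. = FALSE)
  if (L1 != round(L1) || L2 != round(L2))
    stop("amplicon lengths must be integers (base pairs)", call. = FALSE)
  if (!(L1 > L2 && L2 > 1))
    stop("amplicon lengths must satisfy L1 > L2 > 1", call. = FALSE)
  structure(
    list(L1 = as.integer(L1), L2 = as.integer(L2),
         name_long = name_long, name_short = name_short),
    class = "amplicon_pair"
  )
}

#' @export
print.amplicon_pair <- function(x, ...) {
  cat("Amplicon pair: ", x$name_long, " (", x$L1, " bp) / ",
      x$name_short, " (", x$L2, " bp)\n", sep = "")
  invisible(x)
}

.check_copies <- function(N1, N2) {
  if (any(!is.finite(N1)) || any(!is.finite(N2)) ||
      any(N1 <= 0) || any(N2 <= 0))
    stop("copy numbers must be finite and strictly positive", call. = FALSE)
}

#' Per-position survival probability from two amplicon copy numbers
#'
#' Estimates the probability that a given internucleotide position is intact,
#' `p_uncut = (N1/N2)^(1/(L1 - L2))`, from the amplifiable copy numbers of the
#' long (`N1`) and short (`N2`) amplicon. The ratio cancels the DNA recovery,
#' which is why the two-amplicon design is preferred over single-amplicon
#' quantification. Computation is in log domain so extreme copy numbers do
#' not overflow.
#'
#' Measurement noise can produce `N1 > N2` and hence estimates above 1; these
#' are returned unclamped (clamping would bias downstream rate fits). Use
#' [breakage_estimate()] to obtain a quality flag alongside the value.
#'
#' @param N1,N2 Amplifiable copies of the long and short amplicon
#'   (positive reals; qPCR outputs are non-integer). Vectorised.
#' @param pair An [amplicon_pair()].
#'
#' @return Numeric vector of per-position survival probabilities.
#' @examples
#' p_uncut_from_copies(500, 500, amplicon_pair(1064, 93)) # 1: no cutting seen
#' @export
p_uncut_from_copies <- function(N1, N2, pair = amplicon_pair()) {
  stopifnot(inherits(pair, "amplicon_pair"))
  .check_copies(N1, N2)
  exp((log(N1) - log(N2)) / (pair$L1 - pair$L2))
}

#' Estimated total genome copies from two amplicon copy numbers
#'
#' Inverts the forward model `N_i = N * p^(L_i - 1)` for the total genomic
#' copy number `N`, equivalently
#' `N = (N2^(L1 - 1) / N1^(L2 - 1))^(1/(L1 - L2))`. Together with
#' [p_uncut_from_copies()] this reproduces both observed copy numbers exactly.
#'
#' @inheritParams p_uncut_from_copies
#' @return Numeric vector of estimated genome copies.
#' @examples
#' genomic_copies(700, 700, amplicon_pair(1064, 93)) # p = 1 so N = N1 = 700
#' @export
genomic_copies <- function(N1, N2, pair = amplicon_pair()) {
  stopifnot(inherits(pair, "amplicon_pair"))
  .check_copies(N1, N2)
  exp(((pair$L1 - 1) * log(N2) - (pair$L2 - 1) * log(N1)) /
        (pair$L1 - pair$L2))
}

#' Forward model: expected amplifiable copies of one amplicon
#'
#' An L-bp amplicon is amplifiable iff its L - 1 internal positions are all
#' intact, so the expectation is `N0 * p_uncut^(L - 1)`.
#'
#' @param N0 Total genome copies present (>= 0).
#' @param p_uncut Per-position survival probability in \[0, 1\].
#' @param L Amplicon length in base pairs (>= 2).
#' @return Expected amplifiable copy number.
#' @examples
#' amplifiable_copies(1000, 0.999, 93)
#' @export
amplifiable_copies <- function(N0, p_uncut, L) {
  if (any(N0 < 0)) stop("N0 must be non-negative", call. = FALSE)
  if (any(p_uncut < 0 | p_uncut > 1))
    stop("p_uncut must lie in [0, 1]", call. = FALSE)
  if (any(L < 2)) stop("amplicon length must be >= 2", call. = FALSE)
  N0 * p_uncut^(L - 1)
}

#' Genomic DNA recovery fraction
#'
#' Estimated over expected copies. Values above 1 are legal (measurement
#' error routinely produces over-unity recoveries) and are not clipped.
#'
#' @param estimated_copies Estimated genome copies (e.g. [genomic_copies()]).
#' @param expected_copies Expected input copies (> 0).
#' @return Recovery as a fraction (multiply by 100 to display as percent).
#' @export
recovery_fraction <- function(estimated_copies, expected_copies) {
  if (any(expected_copies <= 0))
    stop("expected_copies must be strictly positive", call. = FALSE)
  estimated_copies / expected_copies
}

#' Full breakage estimate with quality flag
#'
#' Combines [p_uncut_from_copies()] and [genomic_copies()] and attaches a
#' quality flag: `"ok"` for estimates in (0, 1\], `"p_above_one"` when noise
#' pushed the survival estimate above 1 (value preserved, not clamped), and
#' `"degenerate"` when the estimate is not a usable finite positive number.
#'
#' @inheritParams p_uncut_from_copies
#' @return An object of class `breakage_estimate` with fields `p_uncut`,
#'   `p_cut`, `genomic_copies` and `flag`.
#' @export
breakage_estimate <- function(N1, N2, pair = amplicon_pair()) {
  p <- p_uncut_from_copies(N1, N2, pair)
  n <- genomic_copies(N1, N2, pair)
  flag <- ifelse(!is.finite(p) | p <= 0, "degenerate",
                 ifelse(p > 1, "p_above_one", "ok"))
  structure(
    list(p_uncut = p, p_cut = 1 - p, genomic_copies = n, flag = flag),
    class = "breakage_estimate"
  )
}

#' @export
print.breakage_estimate <- function(x, ...) {
  cat("Breakage estimate (", length(x$p_uncut), " observation",
      if (length(x$p_uncut) != 1) "s", "):\n", sep = "")
  print(data.frame(p_uncut = x$p_uncut, p_cut = x$p_cut,
                   genomic_copies = x$genomic_copies, flag = x$flag),
        row.names = FALSE)
  invisible(x)
}
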