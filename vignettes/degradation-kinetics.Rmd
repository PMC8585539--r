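---
title: "Estimating DNA degradation rates from two-amplicon qPCR and projecting storage longevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating DNA degradation rates from two-amplicon qPCR and projecting storage longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampdecay)
```

## The model

DNA stored dry in hermetic capsules degrades mainly by random chain
scission. `ampdecay` models scission as a Poisson process acting
independently and identically on every internucleotide position: after time
$t$ at a temperature with per-nucleotide cut rate $k$ (cuts s$^{-1}$
nucleotide$^{-1}$), a given position is intact with probability

$$P_\text{uncut}(t) = e^{-kt}, \qquad P_\text{cut} = 1 - e^{-kt}.$$

An amplicon of length $L$ base pairs amplifies only if all of its $L-1$
internal positions are intact, so the expected amplifiable copy number is
$N_0\,p^{L-1}$ with $p = P_\text{uncut}$. Quantifying **two** amplicons of
different lengths $L_1 > L_2$ at the same locus gives

$$\hat p = \left(\frac{N_1}{N_2}\right)^{1/(L_1 - L_2)}, \qquad
  \hat N_0 = \frac{N_1}{\hat p^{\,L_1 - 1}} =
  \left(\frac{N_2^{\,L_1-1}}{N_1^{\,L_2-1}}\right)^{1/(L_1-L_2)}.$$

The ratio cancels the DNA recovery: multiplying both copy numbers by any
common factor leaves $\hat p$ unchanged, which is the central advantage of
the design over single-amplicon quantification. Both estimators are
computed in log domain so that heavily degraded long-amplicon counts (which
can approach the double-precision floor) do not overflow or underflow.

Per temperature, $-\ln \hat p$ is regressed on $t$; the slope is $k_T$.
Across temperatures the Arrhenius law $k(T) = A\,e^{-E_a/(RT)}$ is fitted
by ordinary least squares of $\ln k_T$ on $1/T$, and the cut rate at the
storage temperature (typically far below the heated range) is obtained by
extrapolation. From that rate the package derives:

* **fragment half-life** $t_{1/2} = \ln 2 / (kL)$ for an $L$-nt fragment
  (survival $e^{-kLt}$),
* **cut budgets** $k \cdot t \cdot n$ over a stated duration and
  nucleotide count,
* **time to a target mean fragment length** from
  $L_\text{max} = 1/P_\text{cut}$, giving
  $t = -\ln(1 - 1/L_\text{max})/k$,
* **minimum-copy retrieval horizon**
  $t = \ln(c_\text{start}/c_\text{min})/(kL)$, the time until intact
  copies of an $L$-nt payload decay from a starting count to the minimum
  needed for faithful decoding.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `L1`, `L2` | 1064, 93 | bp | amplicon lengths; the estimator's exponent is $1/(L_1-L_2)$ |
| gas constant $R$ | 8.314 | J mol$^{-1}$ K$^{-1}$ | fixed |
| Kelvin offset | 273.15 | K | fixed |
| seconds per year | 3.1557e7 | s | Julian year; alternatives change reported years by < 0.1% |
| storage temperature | 25 | °C | extrapolation target |
| fragment length | 150 | nt | half-life comparison size customary in the stability literature |
| target mean length | 25 | nt | practical lower limit for sequencing degraded DNA |
| retrieval copies | 20 → 10 | copies | ten copies is the commonly cited floor for faithful decoding |

Capacity arithmetic uses decimal SI byte multiples throughout (MB =
$10^6$, EB = $10^{18}$, ZB = $10^{21}$); the default capsule holds 200 µL
of DNA at 1.4 g/mL (0.28 g), weighs 1.3 g empty, and stores 17 EB per gram
of DNA with a 3 MB average file size.

## Numerical and design choices

**Through-origin rate fits.** The random-breakage model forces
$P_\text{uncut}(0) = 1$, so the default per-temperature fit constrains the
log-domain regression line through the origin. An unconstrained variant
(`method = "free"`) is exposed because published accelerated-aging fits do
not always state their convention; on clean data the two coincide. A direct
nonlinear fit of $p = e^{-kt}$ is kept in the test suite as an independent
oracle, never used as the implementation.

**Survival estimates above 1.** Measurement noise can make $N_1 > N_2$ and
hence $\hat p > 1$. These values are *retained unclamped* (they contribute
negative $-\ln p$ to the regression) and flagged; clamping at 1 would
truncate the noise distribution one-sidedly and bias every downstream rate
upward. Likewise a negative fitted $k_T$ (possible at the mildest
temperature) is reported with a flag, and the Arrhenius stage excludes
non-positive rates with a logged warning rather than silently zeroing them.

**Bonds versus nucleotides.** The amplifiability exponent is $L-1$ (internal
positions of an $L$-bp amplicon), matching the exponents of the recovery
formula. The longevity projections use $L$ positions at rate $k$ per
nucleotide (survival $e^{-kLt}$), because $k$ is defined per nucleotide;
for a 150-nt fragment at $k = 3.82\times10^{-15}$ the two conventions give
38,300 vs 38,600 years — a difference well inside the uncertainty of any
extrapolation, but the package states its convention and sticks to it.

**Unweighted Arrhenius regression.** The default is plain OLS on
$(1/T, \ln k_T)$; inverse-variance weighting by the delta-method standard
error of $\ln k_T$ is available (`weighted = TRUE`) but not default, since
the per-temperature standard errors from 6-12 points are themselves noisy
and the rate estimates span nine orders of magnitude either way.

**Extrapolation is labelled.** Queries outside the fitted temperature span
return an `extrapolated` marker that propagates into reports and warnings.
Extrapolating from 100-140 °C down to 25 °C is the entire purpose of
accelerated aging — but it amplifies slope error exponentially, so the
label is never dropped.

**Rounding.** Internal chains carry unrounded values; rounding happens only
at report time. This matters in the capacity arithmetic: rounding the DNA
mass for 64 ZB to the nearest gram *before* dividing by the per-capsule
mass changes the capsule count by one. Capsule counts round to nearest by
default, with ceiling as an engineering option.

## What the synthetic generator emulates — and what it does not

`simulate_study()` generates the canonical five-temperature design: 100,
110, 120, 130, 140 °C with 4, 3, 3, 4, 3 time points, 3 capsules per time
point except 2 at 130 °C, and triplicate qPCR per capsule — 47 capsules,
141 records. Per-temperature rates come from a truth Arrhenius law
(default: $E_a$ = 197 kJ/mol anchored at $k(25\,°\text{C}) =
3.82\times10^{-15}$); expected copy numbers follow the forward model with
2530 genome copies per reaction (an 8.35 ng aliquot of human genomic DNA at
~3.3 pg per haploid genome); each replicate measurement is multiplied by
mean-preserving lognormal noise ($\sigma^2 = \ln(1+\text{cv}^2)$, log-mean
$-\sigma^2/2$) with cv 0.15 by default. Noise is lognormal rather than
Poisson because qPCR copy-number error is multiplicative and the estimator
operates on ratios.

Exact heating durations per temperature are rarely published beyond a
range, so the default grids are a modelling choice: time points are placed
geometrically between the moments at which the long amplicon's survival
falls from 80% to 1%, mirroring how electrophoresis pre-screens select
qPCR-suitable durations in practice. At the truth parameters this spans
roughly a quarter of a minute at 140 °C to about 37 h at 100 °C,
consistent with the minutes-to-48 h range of real studies.

The generator does **not** emulate: capsule-to-capsule systematic
variation beyond measurement noise, inhibition or efficiency drift in the
qPCR, base modifications that block the polymerase without breaking the
chain, or non-Arrhenius curvature. A green parameter-recovery test
therefore establishes that the estimation pipeline is consistent and
well-calibrated *under the stated noise model*, not that any particular
laboratory dataset satisfies that model.

## Known limitations and open points

* Two printed longevity figures in the stability literature that motivated
  this package are not reproducible from the printed formulas and rate:
  the time for the mean fragment length to reach 25 nt computes to
  $\approx 3.4\times10^5$ years (not $\sim10^6$), and a 20 → 10 copy
  horizon for 150-nt payloads computes to $\approx 3.8\times10^4$ years
  (not 3,000). The package follows the formulas; both closed forms are
  exposed directly so users can audit the arithmetic.
* Recovery fractions require the expected input copy number per reaction,
  which depends on how input mass maps to genome copies; it is an explicit
  user input, never guessed.
* Extrapolated rates inherit the assumption that a single activated
  process dominates from 140 °C down to storage temperature. The package
  reports $R^2$ of the Arrhenius fit and the extrapolation flag, but
  cannot validate that assumption from accelerated data alone.

## A worked recovery study

```{r recovery, eval = FALSE}
rec <- recover_parameters(n_replicates = 100, seed = 1)
summary(rec$activation_energy) / 1000  # kJ/mol, truth 197
median(rec$k_storage)                  # cuts/s/nt, truth 3.82e-15
```

With the default design and noise, the median recovered activation energy
sits within a fraction of a percent of the truth and the median recovered
storage-temperature rate within a few percent — the acceptance suite
(`tests/testthat/test-acceptance.R`) and `scripts/acceptance.R` recompute
both from scratch.
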