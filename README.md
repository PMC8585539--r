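# ampdecay

Degradation kinetics and longevity projections for DNA preserved in
hermetic capsules, estimated from accelerated-aging qPCR of two amplicons
of different lengths.

## The problem

How stable is dry DNA sealed under inert gas at room temperature? Direct
measurement is impossible — the rates are too low — so stability is
established by accelerated aging: heat sealed capsules at 100–140 °C,
quantify the surviving DNA, fit a rate per temperature, and extrapolate to
storage temperature with the Arrhenius law. `ampdecay` implements that
analysis end to end for anyone validating a DNA preservation process or
sizing a DNA data-storage archive.

The core estimator exploits qPCR of two amplicons of lengths `L1 > L2` at
the same locus. Under random chain scission each internucleotide position
survives with probability `p = e^(-kt)`, an `L`-bp amplicon amplifies with
probability `p^(L-1)`, and so

```
p_uncut = (N1 / N2)^(1 / (L1 - L2))        (recovery cancels in the ratio)
N0      = N1 / p_uncut^(L1 - 1)            (total genome copies)
```

Per temperature, the slope of `-ln p_uncut` against time (constrained
through the origin) gives `k_T`; ordinary least squares of `ln k_T` on
`1/T` gives the activation energy `Ea = -slope * R` and prefactor, from
which the cut rate at any storage temperature follows. Longevity arithmetic
(fragment half-life `ln2/(kL)`, cut budgets, time to a target mean fragment
length, minimum-copy retrieval horizons) and capsule capacity planning
(grams → exabytes → capsule counts → shipment mass) are built on top.

A seeded synthetic-study generator reproduces the canonical experimental
layout (five temperatures, 47 capsules, triplicate qPCR, mean-preserving
lognormal measurement noise) so the whole pipeline is validated by
parameter recovery without any external data.

## Worked example

Simulate a realistic study under a known truth (Ea = 197 kJ/mol, anchored
at k(25 °C) = 3.82e-15 cuts/s/nt, 15% lognormal measurement noise) and run
the full analysis:

```r
library(ampdecay)
truth  <- simulation_truth(noise_cv = 0.15, seed = 42)
study  <- simulate_study(default_study_design(), truth)
report <- run_full_analysis(study)
report
#> Degradation analysis
#> ====================
#> Per-temperature rate constants:
#>  temperature_c            k     k_stderr r_squared n_points flag
#>            100 3.365426e-08 6.213438e-10 0.9962645       12   ok
#>            110 1.720379e-07 2.544506e-09 0.9982530        9   ok
#>            120 8.451280e-07 8.643887e-09 0.9991638        9   ok
#>            130 3.642350e-06 7.006617e-08 0.9974164        8   ok
#>            140 1.555143e-05 2.262545e-07 0.9983095        9   ok
#> Arrhenius model: Ea = 196.5 kJ/mol, ln A = 46.115 (A = 1.07e+20 /s)
#>   fitted on 5 temperatures (100-140 degC), R^2 = 1.0000
#> Rate at 25 degC: 4.02e-15 cuts/s/nt (extrapolated)
#> Longevity at k = 4.02e-15 cuts/s/nt (extrapolated rate)
#>   half-life of a 150-nt fragment:   36000 years
#>   expected cuts per 100 years per 100000 nt: 1.27
#>   time to mean length 25 nt:       320000 years
#>   20 -> 10 copies of 150 nt:         36000 years
#> Warnings:
#>   - 2 survival estimate(s) above 1 retained unclamped
#>   - rate at 25 degC is extrapolated outside the fitted 100-140 degC range
```

The recovered activation energy (196.5 kJ/mol) and storage-temperature
rate (4.02e-15) sit within noise of the generating truth; the two flagged
survival estimates above 1 are the expected tail of 15% multiplicative
noise at the mildest condition, retained unclamped so the fits stay
unbiased. `write_report(report, "report.json")` serialises everything at
full precision.

Capacity planning for one year of global data production:

```r
plan_storage(64e21)   # 64 ZB, default capsule spec
#> Storage plan for 6.4e+22 bytes:
#>   DNA mass:   3765 g
#>   capsules:   13,445 (nearest rounding)
#>   total mass: 21 kg
```

A thin CLI over the same functions ships in `inst/cli/ampdecay.R`
(subcommands `simulate`, `estimate`, `run`, `project`, `capacity`).

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline validation from
scratch: it generates 100 independently seeded synthetic studies under the
default truth and design, runs the full estimation pipeline on each, and
writes the median recovered activation energy (kJ/mol) as JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
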