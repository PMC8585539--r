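Package: ampdecay
Title: Two-Amplicon qPCR Degradation Kinetics and DNA Storage Longevity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-nucleotide DNA chain-scission rates from
    accelerated-aging experiments quantified by qPCR of two amplicons of
    different lengths under a random-breakage model, fits first-order decay
    constants per temperature, extrapolates to storage temperature with the
    Arrhenius law, and derives longevity projections (fragment half-life,
    cut budgets, minimum-copy retrieval horizons) and storage-capacity
    arithmetic for hermetic DNA capsules. Includes a seeded synthetic
    accelerated-aging data generator for end-to-end parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
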