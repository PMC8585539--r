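# Shared fixtures: the canonical amplicon pair and a forward-generated
# noiseless study used across modules.

taf_pair <- amplicon_pair(1064, 93, "TAF1064", "TAF93")

# Noiseless measurements table for arbitrary designs
noiseless_study <- function(seed = 1, cv = 0, ...) {
  truth <- simulation_truth(noise_cv = cv, seed = seed, ...)
  simulate_study(default_study_design(), truth, taf_pair)
}

# Independent NLS oracle: direct nonlinear fit of p = exp(-k t)
nls_rate_oracle <- function(time_s, p_uncut, start_k) {
  fit <- stats::nls(p_uncut ~ exp(-k * time_s), start = list(k = start_k))
  unname(stats::coef(fit)[["k"]])
}
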