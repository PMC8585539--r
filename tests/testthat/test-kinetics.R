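test_that("noiseless exponential decay is fitted exactly", {
  ts <- c(3600, 7200, 14400)
  s <- kinetic_series(120, ts, exp(-1e-5 * ts))
  fit <- fit_rate_constant(s)
  expect_equal(fit$k, 1e-5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_identical(fit$flag, "ok")
  # halving all p at fixed t is not exponential; but doubling times halves k
  s2 <- kinetic_series(120, 2 * ts, exp(-1e-5 * ts))
  expect_equal(fit_rate_constant(s2)$k, 5e-6, tolerance = 1e-12)
})

test_that("undegraded series give k = 0 and inverted ones a flagged negative k", {
  s <- kinetic_series(100, c(600, 1200, 2400), c(1, 1, 1))
  expect_equal(fit_rate_constant(s)$k, 0)
  inv <- kinetic_series(100, c(600, 1200, 2400), c(1.01, 1.03, 1.06))
  fit <- fit_rate_constant(inv)
  expect_lt(fit$k, 0)
  expect_identical(fit$flag, "negative_rate")
})

test_that("origin-constrained fit agrees with a direct NLS oracle under noise", {
  true_k <- 3e-8
  ts <- rep(c(3e6, 1e7, 2e7, 3e7), each = 3)  # kt spans ~0.09-0.9
  withr::with_seed(42, {
    p <- exp(-true_k * ts) * rlnorm(length(ts), 0, 0.1)
  })
  fit <- fit_rate_constant(kinetic_series(100, ts, p))
  k_nls <- nls_rate_oracle(ts, p, start_k = 1e-8)
  expect_lt(abs(fit$k - k_nls), 3 * fit$k_stderr)
})

test_that("free-intercept variant matches the origin fit on clean data", {
  ts <- c(1000, 2000, 4000, 8000)
  s <- kinetic_series(130, ts, exp(-2e-4 * ts))
  expect_equal(fit_rate_constant(s, method = "free")$k, 2e-4,
               tolerance = 1e-10)
})

test_that("build_series groups by temperature with geometric-mean replicates", {
  m <- data.frame(
    temperature_c = rep(c(110, 120), each = 6),
    time_s = rep(c(100, 200, 100, 200), each = 3),
    capsule_id = rep(c("a", "b", "c", "d"), each = 3),
    n_long = rep(c(100, 50, 80, 40), each = 3) * c(0.5, 1, 2),
    n_short = rep(200, 12)
  )
  series <- build_series(m, taf_pair)
  expect_length(series, 2)
  expect_equal(vapply(series, function(s) nrow(s$points), 0L), c(2L, 2L))
  # geometric mean of {50, 100, 200} is 100
  p_expect <- p_uncut_from_copies(100, 200, taf_pair)
  expect_equal(series[[1]]$points$p_uncut[1], p_expect, tolerance = 1e-12)
})

test_that("the default five-temperature design yields the expected series shapes", {
  series <- build_series(noiseless_study(), taf_pair)
  expect_length(series, 5)
  expect_equal(vapply(series, `[[`, 0, "temperature_c"),
               c(100, 110, 120, 130, 140))
  # points per series = time points x capsules
  expect_equal(vapply(series, function(s) nrow(s$points), 0L),
               c(4L, 3L, 3L, 4L, 3L) * c(3L, 3L, 3L, 2L, 3L))
  # distinct time points per temperature follow the design
  expect_equal(vapply(series, function(s) length(unique(s$points$time_s)), 0L),
               c(4L, 3L, 3L, 4L, 3L))
})

test_that("fitted k on noiseless forward data matches truth at every temperature", {
  study <- noiseless_study()
  truth <- attr(study, "truth")
  for (s in build_series(study, taf_pair)) {
    k_true <- as.numeric(rate_at(truth$model, s$temperature_c))
    expect_equal(fit_rate_constant(s)$k, k_true, tolerance = 1e-8)
  }
})

test_that("fitted k is invariant to common rescaling of both amplicons", {
  study <- noiseless_study(cv = 0.1)
  k0 <- vapply(build_series(study, taf_pair), function(s)
    fit_rate_constant(s)$k, 0)
  study$n_long <- study$n_long * 17.3
  study$n_short <- study$n_short * 17.3
  k1 <- vapply(build_series(study, taf_pair), function(s)
    fit_rate_constant(s)$k, 0)
  expect_equal(k1, k0, tolerance = 1e-12)
})

test_that("degenerate kinetic inputs are rejected", {
  expect_error(fit_rate_constant(kinetic_series(100, c(0, 0), c(1, 0.9))),
               "t > 0")
  expect_error(fit_rate_constant(kinetic_series(100, c(10, 20), c(1, 0))),
               "positive")
  expect_error(build_series(data.frame(), taf_pair), "column")
})
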