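k25 <- 3.82e-15  # extrapolated storage-temperature rate used as scenario input

test_that("half-life follows ln2/(kL) with the stated year convention", {
  expect_equal(fragment_half_life(k25, 150),
               log(2) / (k25 * 150) / 3.1557e7, tolerance = 1e-12)
  # inverse proportionality in k and L
  expect_equal(fragment_half_life(2 * k25, 150),
               fragment_half_life(k25, 150) / 2, tolerance = 1e-12)
  expect_equal(fragment_half_life(k25, 1),
               log(2) / k25 / 3.1557e7, tolerance = 1e-12)
  expect_error(fragment_half_life(0, 150), "positive")
})

test_that("cut budgets are linear in time and nucleotide count", {
  base <- expected_cuts(k25, 100, 1e5)
  expect_equal(expected_cuts(k25, 100, 2e5), 2 * base, tolerance = 1e-12)
  expect_equal(expected_cuts(k25, 200, 1e5), 2 * base, tolerance = 1e-12)
  expect_equal(expected_cuts(k25, 0, 1e5), 0)
})

test_that("time to a target mean fragment length follows the scission formula", {
  t25 <- time_to_mean_length(k25, 25)
  expect_equal(t25, -log(1 - 1 / 25) / k25 / 3.1557e7, tolerance = 1e-12)
  # small-kt expansion: t ~ 1/(k * target) within 2% for target >= 25
  expect_equal(t25 * k25 * 3.1557e7 * 25, 1, tolerance = 0.025)
  # longer targets are reached sooner
  expect_lt(time_to_mean_length(k25, 100), t25)
  expect_error(time_to_mean_length(k25, 1), "exceed 1")
})

test_that("retrieval horizon is first-order decay of intact copies", {
  expect_equal(retrieval_horizon(k25, 150, 20, 10),
               log(2) / (k25 * 150) / 3.1557e7, tolerance = 1e-12)
  # e-fold with L = 1 gives 1/k seconds
  expect_equal(retrieval_horizon(k25, 1, exp(1) * 10, 10) * 3.1557e7,
               1 / k25, tolerance = 1e-9)
  expect_error(retrieval_horizon(k25, 150, 10, 10), "copies_start")
})

test_that("half-life and 2:1 retrieval horizon are the same quantity", {
  set.seed(3)
  for (i in 1:10) {
    k <- 10^runif(1, -16, -6); L <- sample(1:1000, 1)
    expect_equal(fragment_half_life(k, L), retrieval_horizon(k, L, 2, 1),
                 tolerance = 1e-12)
  }
})

test_that("cut budget over one half-life equals ln2 * n/L; outputs scale as 1/k", {
  k <- 1e-12; L <- 300; n_nt <- 9e5
  hl <- fragment_half_life(k, L)
  expect_equal(expected_cuts(k, hl, n_nt), log(2) * n_nt / L,
               tolerance = 1e-12)
  for (c in c(0.1, 10)) {
    expect_equal(fragment_half_life(c * k, L), fragment_half_life(k, L) / c,
                 tolerance = 1e-12)
    expect_equal(time_to_mean_length(c * k, 25),
                 time_to_mean_length(k, 25) / c, tolerance = 1e-12)
    expect_equal(retrieval_horizon(c * k, L, 20, 10),
                 retrieval_horizon(k, L, 20, 10) / c, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo fragment survival matches the closed form", {
  cases <- list(c(k = 1e-6, L = 150, t = log(2) / (1e-6 * 150)),  # kLt = ln2
                c(k = 1e-8, L = 500, t = 1e5),
                c(k = 5e-7, L = 50, t = 2e6))
  withr::with_seed(99, {
    for (cs in cases) {
      n <- 1e5
      intact <- simulate_fragment_population(n, cs["L"], cs["k"], cs["t"])
      p <- exp(-cs[["k"]] * cs[["L"]] * cs[["t"]])
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(intact) - p), 3 * se)
    }
  })
  # the ln2 case specifically: intact fraction 0.5 within 0.005
  withr::with_seed(100, {
    frac <- mean(simulate_fragment_population(1e5, 150, 1e-6,
                                              log(2) / (1e-6 * 150)))
  })
  expect_lt(abs(frac - 0.5), 0.005)
})

test_that("survival decreases with fragment length at fixed exposure", {
  withr::with_seed(5, {
    fr <- vapply(c(50, 150, 500), function(L)
      mean(simulate_fragment_population(2e4, L, 1e-7, 1e5)), 0)
  })
  expect_true(all(diff(fr) < 0))
  expect_true(all(simulate_fragment_population(100, 150, 1e-7, 0)))
})

test_that("the longevity report bundles the projections consistently", {
  rep <- longevity_report(k25)
  expect_equal(rep$half_life_years, fragment_half_life(k25, 150))
  expect_equal(rep$cuts_per_interval, expected_cuts(k25, 100, 1e5))
  expect_equal(rep$t_to_mean_length_years, time_to_mean_length(k25, 25))
  expect_equal(rep$retrieval_horizon_years,
               retrieval_horizon(k25, 150, 20, 10))
})
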