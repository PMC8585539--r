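test_that("measurements round-trip through CSV unchanged", {
  study <- noiseless_study(cv = 0.1, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(study, path)
  back <- read_measurements(path)
  cols <- c("temperature_c", "time_s", "capsule_id", "replicate_id",
            "n_long", "n_short")
  expect_equal(back[cols], study[cols], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("time units convert and schema violations name their lines", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "temperature_c,time_value,time_unit,capsule_id,replicate_id,n_long,n_short",
    "100,2,h,a,1,500,900",
    "100,30,min,b,1,400,900",
    "100,7200,s,c,1,500,900"), path)
  m <- read_measurements(path)
  expect_equal(m$time_s, c(7200, 1800, 7200))

  writeLines(c(
    "temperature_c,time_value,time_unit,capsule_id,replicate_id,n_long,n_short",
    "100,2,days,a,1,500,900"), path)
  expect_error(read_measurements(path), "time_unit at line\\(s\\) 2")

  writeLines(c(
    "temperature_c,time_value,time_unit,capsule_id,replicate_id,n_long,n_short",
    "100,2,h,a,1,500,900",
    "100,x,h,b,1,500,900"), path)
  expect_error(read_measurements(path), "time_value at line\\(s\\) 3")

  writeLines("temperature_c,time_value,time_unit,capsule_id,replicate_id,n_long,n_short",
             path)
  expect_error(read_measurements(path), "no data rows")

  writeLines(c(
    "temperature_c,time_value,time_unit,capsule_id,replicate_id,n_long,n_short,extra",
    "100,2,h,a,1,500,900,zzz",
    "100,4,h,b,1,400,900,zzz"), path)
  expect_warning(m <- read_measurements(path), "unknown column")
  expect_false("extra" %in% names(m))
})

test_that("the full analysis reproduces truth on a noiseless study", {
  study <- noiseless_study(seed = 31)
  truth <- attr(study, "truth")
  report <- run_full_analysis(study, taf_pair)
  expect_s3_class(report, "degradation_report")
  expect_equal(report$arrhenius$activation_energy, truth$activation_energy,
               tolerance = 1e-6)
  expect_equal(report$storage$k, truth$k_reference, tolerance = 1e-6)
  expect_true(report$storage$extrapolated)  # 25 degC is below 100-140
  expect_true(any(grepl("extrapolated", report$warnings)))
  expect_equal(nrow(report$kinetic_fits), 5)
  # longevity block is computed from the recovered storage rate
  expect_equal(report$longevity$half_life_years,
               fragment_half_life(report$storage$k, 150), tolerance = 1e-12)
})

test_that("analysis runs from a CSV path and a degraded design with a warning trail", {
  study <- noiseless_study(cv = 0.15, seed = 41)
  partial <- study[study$temperature_c != 140, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(partial, path)
  report <- run_full_analysis(path, taf_pair)
  expect_equal(report$arrhenius$n_temperatures, 4L)
  expect_equal(report$arrhenius$activation_energy, 197e3, tolerance = 0.15)
})

test_that("recovery tables appear when expected copies are supplied", {
  study <- noiseless_study(seed = 51)
  report <- run_full_analysis(study, taf_pair, expected_copies = 2530)
  expect_false(is.null(report$recovery))
  # noiseless data: recovery is exactly 1 everywhere
  expect_equal(report$recovery$recovery, rep(1, nrow(report$recovery)),
               tolerance = 1e-9)
})

test_that("reports serialise deterministically with full precision", {
  study <- noiseless_study(cv = 0.15, seed = 61)
  report <- run_full_analysis(study, taf_pair)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(report, p1)
  write_report(report, p2)
  expect_identical(readLines(p1), readLines(p2))
  parsed <- jsonlite::fromJSON(p1)
  expect_equal(parsed$arrhenius$activation_energy_kj_mol,
               report$arrhenius$activation_energy / 1000, tolerance = 1e-12)
  expect_equal(parsed$storage$k, report$storage$k, tolerance = 1e-12)
})

test_that("warning pathways: p > 1 and negative rates are surfaced", {
  # inverted decay at one temperature forces p > 1 and a negative k there
  m <- data.frame(
    temperature_c = rep(c(100, 120, 140), each = 4),
    time_s = rep(c(1e3, 2e3, 4e3, 8e3), 3),
    capsule_id = paste0("c", 1:12),
    replicate_id = 1L,
    n_long = NA_real_, n_short = 900
  )
  k_by_temp <- c(`100` = -1e-7, `120` = 1e-5, `140` = 2e-5)
  p <- exp(-k_by_temp[as.character(m$temperature_c)] * m$time_s)
  m$n_long <- m$n_short * p^(taf_pair$L1 - taf_pair$L2)
  report <- run_full_analysis(m, taf_pair)
  expect_true(any(grepl("above 1", report$warnings)))
  expect_true(any(grepl("non-positive rate", report$warnings)))
  expect_equal(report$arrhenius$n_temperatures, 2L)
})
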