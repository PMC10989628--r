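test_that("generators are pure functions of spec and seed", {
  expect_identical(simulate_array(array_spec(), seed = 5),
                   simulate_array(array_spec(), seed = 5))
  arr <- simulate_array(array_spec(), seed = 5)
  expect_identical(simulate_calibration(arr, calibration_design(), seed = 6),
                   simulate_calibration(arr, calibration_design(), seed = 6))
  expect_identical(
    simulate_sample_emfs(arr, drift_model("occasion_offset", 10), c(1e-4, 1e-3), seed = 7),
    simulate_sample_emfs(arr, drift_model("occasion_offset", 10), c(1e-4, 1e-3), seed = 7))
  expect_identical(simulate_comparison_table(comparison_scenario(), seed = 8),
                   simulate_comparison_table(comparison_scenario(), seed = 8))
  # and they leave the caller's RNG stream untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_array(array_spec(), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("degenerate population sds give identical electrodes", {
  arr <- simulate_array(array_spec(E0_sd = 0, slope_sd = 0, log10Kbg_sd = 0),
                        seed = 1)
  expect_equal(nrow(arr), 4)
  expect_equal(length(unique(arr$E0)), 1)
  expect_equal(length(unique(arr$slope)), 1)
  expect_equal(length(unique(arr$K_bg)), 1)
})

test_that("drawn electrode populations have the specified spread", {
  arr <- simulate_array(array_spec(n_electrodes = 1e4, E0_sd = 5), seed = 42)
  expect_equal(stats::sd(arr$E0), 5, tolerance = 0.15 / 5)
})

test_that("noiseless calibration reproduces the forward model exactly", {
  p <- electrode_params(200, 57, 10^-5.5, sigma = 0)
  cal <- simulate_calibration(p, calibration_design(), seed = 3)
  mu <- nikolsky_emf(p, 10^cal$log10_conc)
  expect_lt(max(abs(cal$emf_mV - mu)), 1e-9)
})

test_that("calibration noise has the nominal standard deviation", {
  p <- electrode_params(200, 57, 0, sigma = 1)
  cal <- simulate_calibration(p, calibration_design(log10_conc_steps = c(-4, -3, -2),
                                                    replicates = 1000), seed = 9)
  res <- cal$emf_mV - nikolsky_emf(p, 10^cal$log10_conc)
  expect_equal(stats::sd(res), 1, tolerance = 0.07)
})

test_that("background flattens the low end of the calibration curve", {
  p <- electrode_params(200, 57, 10^-5.5, sigma = 0)
  cal <- simulate_calibration(p, calibration_design(seq(-6, -2, 1)), seed = 2)
  e <- cal$emf_mV[order(cal$log10_conc)]
  expect_lt(e[2] - e[1], e[5] - e[4])
})

test_that("occasion drift produces the folded-normal inversion error", {
  p <- electrode_params(200, 59.16, 0, sigma = 0)
  n <- 1000
  sam <- simulate_sample_emfs(p, drift_model("occasion_offset", 10),
                              rep(1e-4, n), seed = 13)
  x_hat <- (sam$emf_mV - p$E0) / p$slope
  err <- abs(x_hat - (-4))
  expect_equal(mean(err), 10 * sqrt(2 / pi) / 59.16, tolerance = 0.015 / 0.135)
})

test_that("linear drift adds rate * time to the baseline", {
  p <- electrode_params(200, 59.16, 0, sigma = 0)
  sam <- simulate_sample_emfs(p, drift_model("linear", rate = 2),
                              rep(1e-4, 3), seed = 1, t_hours = 1:3)
  base <- nikolsky_emf(p, 1e-4)
  expect_equal(sam$emf_mV - base, c(2, 4, 6), tolerance = 1e-12)
})

test_that("standard-addition series follow volume-corrected arithmetic", {
  p <- electrode_params(200, 59.16, 0, sigma = 0)
  sched0 <- addition_schedule(100, numeric(0), numeric(0))
  s0 <- simulate_standard_addition(p, sched0, 1e-4, drift_model("none"), seed = 1)
  expect_equal(nrow(s0), 1)
  expect_equal(s0$emf_mV, nikolsky_emf(p, 1e-4))

  sched <- addition_schedule(100, 1, 0.01)
  s1 <- simulate_standard_addition(p, sched, 1e-4, drift_model("none"), seed = 1)
  dE <- diff(s1$emf_mV)
  expect_equal(dE, 59.16 * log10(1.9802), tolerance = 0.05 / 17.55)

  # a baseline offset shifts every step equally, so emf differences cancel
  p_off <- electrode_params(210, 59.16, 0, sigma = 0)
  s2 <- simulate_standard_addition(p_off, sched, 1e-4, drift_model("none"), seed = 1)
  expect_equal(diff(s2$emf_mV), dE, tolerance = 1e-12)
})

test_that("comparison tables encode recovery and correlate as constructed", {
  exact <- comparison_scenario(measurement_cv = 0, recovery_A = 1, recovery_B = 1)
  tab <- simulate_comparison_table(exact, seed = 4)
  pairs <- pair_comparison(tab)
  expect_equal(pairs$value_A, pairs$value_B)
  expect_equal(pearson_with_p(pairs)$r, 1, tolerance = 1e-12)

  rec <- comparison_scenario(measurement_cv = 0, recovery_B = 0.98)
  tabr <- pair_comparison(simulate_comparison_table(rec, seed = 4))
  st <- recovery_stats(tabr)
  expect_equal(st$mean, 98, tolerance = 1e-9)
  expect_equal(st$sd, 0, tolerance = 1e-9)

  noisy <- pair_comparison(simulate_comparison_table(comparison_scenario(), seed = 7))
  expect_gte(pearson_with_p(noisy)$r, 0.99)
})

test_that("generated tables pass the CSV schemas unchanged", {
  arr <- simulate_array(array_spec(n_electrodes = 2), seed = 5)
  cal <- simulate_calibration(arr, calibration_design(), seed = 6)
  sam <- simulate_sample_emfs(arr, drift_model("none"), c(1e-4, 1e-3), seed = 7)
  sa <- simulate_sa_table(arr, default_sa_schedule(), c(1e-4), drift_model("none"), seed = 8)
  cmp <- simulate_comparison_table(comparison_scenario(n_samples = 4), seed = 9)
  td <- withr::local_tempdir()
  expect_equal(
    read_calibration_csv(write_ise_csv(cal, file.path(td, "c.csv"), "calibration")),
    cal[, c("electrode_id", "log10_conc", "emf_mV")], tolerance = 1e-12)
  expect_equal(
    read_sample_csv(write_ise_csv(sam, file.path(td, "s.csv"), "sample")),
    sam[, c("sample_id", "electrode_id", "occasion", "emf_mV")],
    tolerance = 1e-12)
  expect_equal(
    read_sa_csv(write_ise_csv(sa, file.path(td, "a.csv"), "standard_addition")),
    sa[, c("sample_id", "electrode_id", "step", "initial_volume_mL",
           "added_volume_mL", "standard_conc_M", "emf_mV")], tolerance = 1e-12)
  expect_equal(
    read_comparison_csv(write_ise_csv(cmp, file.path(td, "m.csv"), "comparison")),
    cmp[, c("sample_id", "analyte", "method", "conc_ppm")], tolerance = 1e-12)
})
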