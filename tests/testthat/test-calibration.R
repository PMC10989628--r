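test_that("noise-free calibration recovers the generating parameters", {
  p <- electrode_params(200, 57, 10^-5.5, sigma = 0)
  cal <- simulate_calibration(p, calibration_design(), seed = 1)
  post <- fit_single(cal, settings = quick_settings(2))
  d <- diagnostics_report(post)
  med <- function(par) d$median[d$parameter == par]
  expect_lt(abs(med("E0") - 200), 0.5)
  expect_lt(abs(med("S") - 57), 0.5)
  expect_lt(abs(med("logK") - (-5.5)), 0.1)
})

test_that("fit_array with one electrode matches fit_single", {
  fx <- cached_array_fit()
  one <- fx$calibration[fx$calibration$electrode_id == "ISE1", ]
  ps <- fit_single(one, settings = quick_settings(21))
  pa <- fit_array(list(ISE1 = one[, c("log10_conc", "emf_mV")]),
                  settings = quick_settings(22))
  ds <- diagnostics_report(ps)
  da <- diagnostics_report(pa)
  for (par in c("E0", "S", "logK")) {
    s <- ds[ds$parameter == par, ]
    a <- da[da$parameter == par, ]
    mcse <- (s$q97.5 - s$q2.5) / 3.92 / sqrt(max(s$ess, 10))
    expect_lt(abs(s$median - a$median), 6 * mcse + 1e-8)
  }
})

test_that("identical noiseless electrodes get identical marginal posteriors", {
  arr <- simulate_array(array_spec(E0_sd = 0, slope_sd = 0, noise_sd = 0),
                        seed = 1)
  cal <- simulate_calibration(arr, calibration_design(), seed = 2)
  post <- fit_array(cal, settings = quick_settings(5))
  d <- diagnostics_report(post)
  for (par in c("E0", "S", "logK")) {
    meds <- d$median[d$parameter == par]
    expect_lt(diff(range(meds)), 0.01)
  }
})

test_that("a noisy electrode is identified by its sigma posterior", {
  arr <- data.frame(electrode_id = paste0("ISE", 1:4), E0 = 200, slope = 57,
                    K_bg = 10^-5.5, sigma = c(5, 0.5, 0.5, 0.5))
  class(arr) <- c("ise_array", "data.frame")
  cal <- simulate_calibration(arr, calibration_design(replicates = 3), seed = 3)
  post <- fit_array(cal, settings = quick_settings(3))
  d <- diagnostics_report(post)
  sig <- d[d$parameter == "sigma", ]
  noisy <- sig$median[sig$electrode_id == "ISE1"]
  others <- sig$median[sig$electrode_id != "ISE1"]
  expect_true(all(noisy >= 5 * others))
})

test_that("without low-concentration data the background posterior stays at its prior", {
  cal <- simulate_calibration(electrode_params(200, 57, 1e-8, 1),
                              calibration_design(seq(-3, -1, length.out = 6)),
                              seed = 4)
  post <- fit_single(cal, priors = prior_spec(logK_lower = -9, logK_upper = -5),
                     settings = quick_settings(4, draws = 2000))
  d <- diagnostics_report(post)
  lk <- d[d$parameter == "logK", ]
  expect_gte((lk$q97.5 - lk$q2.5) / (-5 - (-9)), 0.8)
})

test_that("degenerate or insufficient calibration data are rejected", {
  flat <- data.frame(electrode_id = "ISE1", log10_conc = seq(-6, -2, 1),
                     emf_mV = rep(100, 5))
  expect_error(fit_single(flat), "degenerate")
  short <- data.frame(log10_conc = c(-4, -3, -2), emf_mV = c(1, 2, 3))
  expect_error(fit_single(short), ">= 4 records")
  narrow <- data.frame(log10_conc = seq(-3, -2.5, length.out = 5),
                       emf_mV = 1:5)
  expect_error(fit_single(narrow), "2 decades")
})

test_that("diagnostics report nests intervals, mixes well and survives constant chains", {
  fx <- cached_array_fit()
  d <- diagnostics_report(fx$posterior)
  expect_true(all(d$q25 >= d$q2.5 & d$q75 <= d$q97.5))
  expect_true(all(d$median >= d$q25 & d$median <= d$q75))
  expect_true(all(is.na(d$rhat) | d$rhat < 1.05))
  expect_true(all(d$ess > 50, na.rm = TRUE))
  # constant chains: R-hat undefined (NA), no error
  const <- degenerate_posterior(electrode_params(200, 57, 1e-5, 1), 200)
  dc <- diagnostics_report(const)
  expect_true(all(is.na(dc$rhat)))
})

test_that("posterior predictive intervals cover held-out calibration data", {
  fx <- cached_array_fit()
  arr1 <- fx$array[1, ]
  held <- simulate_calibration(arr1,
                               calibration_design(replicates = 12), seed = 77)
  d <- fx$posterior$draws[["ISE1"]]
  covered <- 0
  set.seed(31)
  for (i in seq_len(nrow(held))) {
    mu <- d$E0 + d$S * log10(10^held$log10_conc[i] + 10^d$logK)
    pred <- mu + stats::rnorm(length(mu), 0, d$sigma)
    q <- stats::quantile(pred, c(0.025, 0.975))
    covered <- covered + (held$emf_mV[i] >= q[1] && held$emf_mV[i] <= q[2])
  }
  rate <- covered / nrow(held)
  expect_gte(nrow(held), 100)
  expect_gte(rate, 0.88)
})

test_that("doubling calibration replicates tightens the slope posterior", {
  shrunk <- 0
  for (s in 1:10) {
    arr <- simulate_array(array_spec(n_electrodes = 1), seed = 100 + s)
    cal1 <- simulate_calibration(arr, calibration_design(replicates = 1),
                                 seed = 200 + s)
    cal2 <- simulate_calibration(arr, calibration_design(replicates = 2),
                                 seed = 300 + s)
    f1 <- fit_array(cal1, settings = quick_settings(400 + s))
    f2 <- fit_array(cal2, settings = quick_settings(500 + s))
    sd1 <- stats::sd(f1$draws[[1]]$S)
    sd2 <- stats::sd(f2$draws[[1]]$S)
    shrunk <- shrunk + (sd2 < sd1)
  }
  expect_gte(shrunk, 8)
})

test_that("slope recovery across the default scenario is accurate and calibrated", {
  st <- cached_recovery_study()
  expect_equal(nrow(st), 20)
  expect_lt(stats::median(abs(st$S_median - st$S_true)), 1)
})
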