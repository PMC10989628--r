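test_that("volume correction follows total-mass bookkeeping", {
  sched <- addition_schedule(100, 1, 0.01)
  expect_identical(volume_corrected_conc(1e-4, sched, 0), 1e-4)
  expect_equal(volume_corrected_conc(1e-4, sched, 1), 1.9802e-4,
               tolerance = 1e-8 / 1.98e-4)
  # spiking with the sample's own concentration changes nothing
  fix <- addition_schedule(100, 5, 1e-4)
  expect_equal(volume_corrected_conc(1e-4, fix, 1), 1e-4, tolerance = 1e-15)
  expect_error(volume_corrected_conc(1e-4, sched, 2), "outside")
})

test_that("classical standard addition inverts the forward model", {
  sched <- addition_schedule(100, 1, 0.01)
  p <- electrode_params(200, 59.16, 0, 0)
  c0 <- 1e-4
  e0 <- nikolsky_emf(p, c0)
  e1 <- nikolsky_emf(p, volume_corrected_conc(c0, sched, 1))
  expect_equal(classical_standard_addition(e0, e1, p$slope, sched), c0,
               tolerance = 1e-4)
  # symbolic round-trip at random parameter sets
  set.seed(8)
  for (i in 1:3) {
    v0 <- stats::runif(1, 50, 200)
    v1 <- stats::runif(1, 0.5, 5)
    cs <- 10^stats::runif(1, -3, -1)
    c0i <- 10^stats::runif(1, -5, -3)
    s <- stats::runif(1, 50, 60)
    sc <- addition_schedule(v0, v1, cs)
    dE <- s * log10((v0 * c0i + v1 * cs) / (c0i * (v0 + v1)))
    expect_equal(classical_standard_addition(0, dE, s, sc), c0i,
                 tolerance = 1e-9)
  }
  # dE = 0 forces the fixed point c0 = c_std
  expect_equal(classical_standard_addition(50, 50, 59.16, sched), 0.01,
               tolerance = 1e-12)
  # emf drop after adding standard is inconsistent with a positive c0
  expect_error(classical_standard_addition(50, 20, 59.16, sched),
               "inconsistent")
})

test_that("direct potentiometry inverts exactly for a degenerate noise-free posterior", {
  post <- degenerate_posterior(electrode_params(200, 57, 10^-5.5, 0), 200)
  emf <- 200 + 57 * log10(1e-4 + 10^-5.5)
  ms <- data.frame(sample_id = "S1", electrode_id = "ISE1", occasion = 1,
                   emf_mV = emf)
  est <- estimate_direct(post, ms, analyte_nh4(), seed = 5)
  expect_equal(est$est_log10M, -4, tolerance = 0.001 / 4)
  expect_false(est$censored)
  # estimation is reproducible for a fixed seed
  expect_identical(est, estimate_direct(post, ms, analyte_nh4(), seed = 5))
})

test_that("readings below the blank response are censored, not errors", {
  p <- electrode_params(200, 57, 10^-5.5, 0.5)
  post <- degenerate_posterior(p, 200)
  blank <- nikolsky_emf(p, 0)
  ms <- data.frame(sample_id = "S1", electrode_id = "ISE1", occasion = 1,
                   emf_mV = blank - 20)
  est <- estimate_direct(post, ms, analyte_nh4(), seed = 2)
  expect_true(est$censored)
  expect_gt(est$censored_frac, 0.99)
  # pinned at the background level: an upper-bound-style estimate
  expect_equal(est$est_log10M, -5.5, tolerance = 1e-6)
})

test_that("Bayesian standard addition agrees with the classical closed form", {
  p <- electrode_params(200, 57, 1e-9, 0)
  post <- degenerate_posterior(p, 200)
  sched <- addition_schedule(100, 1, 0.01)
  tab <- simulate_standard_addition(p, sched, 1e-4, drift_model("none"), seed = 3)
  est <- estimate_standard_addition(post, tab, analyte_nh4(), seed = 4)
  oracle <- classical_standard_addition(tab$emf_mV[1], tab$emf_mV[2], p$slope,
                                        sched)
  expect_equal(10^est$est_log10M, oracle, tolerance = 0.005)
})

test_that("standard addition is immune to baseline offsets, direct potentiometry is not", {
  p <- electrode_params(200, 57, 1e-9, 0)
  post <- degenerate_posterior(p, 200)
  sched <- default_sa_schedule()
  base <- simulate_standard_addition(p, sched, 1e-4, drift_model("none"), seed = 6)
  for (off in c(25, 10, -10)) {
    shifted <- base
    shifted$emf_mV <- base$emf_mV + off
    est <- estimate_standard_addition(post, shifted, analyte_nh4(), seed = 7)
    est0 <- estimate_standard_addition(post, base, analyte_nh4(), seed = 7)
    expect_equal(est$est_log10M, est0$est_log10M, tolerance = 1e-9)
    expect_equal(10^est$est_log10M, 1e-4, tolerance = 1e-3)
  }
  # the same offset shifts a direct estimate by offset/S decades
  emf <- nikolsky_emf(p, 1e-4)
  dp0 <- estimate_direct(post, data.frame(sample_id = "S1", electrode_id = "ISE1",
                                          occasion = 1, emf_mV = emf),
                         analyte_nh4(), seed = 8)
  dp1 <- estimate_direct(post, data.frame(sample_id = "S1", electrode_id = "ISE1",
                                          occasion = 1, emf_mV = emf + 10),
                         analyte_nh4(), seed = 8)
  expect_equal(dp1$est_log10M - dp0$est_log10M, 10 / 57, tolerance = 0.01)
})

test_that("pooling four identical-quality electrodes halves the interval width", {
  # exchangeable electrodes: identical parameter uncertainty and noise
  set.seed(17)
  n <- 2000
  draws <- lapply(1:4, function(i) {
    data.frame(E0 = stats::rnorm(n, 200, 1), S = stats::rnorm(n, 57, 0.5),
               logK = stats::rnorm(n, -5.5, 0.05), sigma = rep(1, n))
  })
  names(draws) <- paste0("ISE", 1:4)
  post <- new_ise_posterior(draws)
  arr <- data.frame(electrode_id = paste0("ISE", 1:4), E0 = 200, slope = 57,
                    K_bg = 10^-5.5, sigma = 1)
  class(arr) <- c("ise_array", "data.frame")
  sam <- simulate_sample_emfs(arr, drift_model("none"), rep(1e-4, 20), seed = 8)
  w4 <- estimate_direct(post, sam, analyte_nh4(), seed = 11)$width95_log10
  w1 <- estimate_direct(post, sam[sam$electrode_id == "ISE1", ],
                        analyte_nh4(), seed = 12)$width95_log10
  expect_equal(mean(w4) / mean(w1), 0.5, tolerance = 0.15)
})

test_that("estimate summaries nest intervals and match their ppm conversions", {
  fx <- cached_array_fit()
  sam <- simulate_sample_emfs(fx$array, drift_model("occasion_offset", 10),
                              10^seq(-5, -3, length.out = 6), seed = 21)
  est <- estimate_direct(fx$posterior, sam, analyte_nh4(), drift_sd = 10,
                         seed = 22)
  expect_true(all(est$q2.5_log10M <= est$q25_log10M))
  expect_true(all(est$q25_log10M <= est$est_log10M))
  expect_true(all(est$est_log10M <= est$q75_log10M))
  expect_true(all(est$q75_log10M <= est$q97.5_log10M))
  expect_equal(est$est_ppm, molar_to_ppm(10^est$est_log10M, analyte_nh4()),
               tolerance = 1e-12)
  tab <- simulate_sa_table(fx$array, default_sa_schedule(),
                           10^seq(-5, -3, length.out = 4),
                           drift_model("occasion_offset", 10), seed = 23)
  esa <- estimate_standard_addition(fx$posterior, tab, analyte_nh4(), seed = 24)
  expect_true(all(esa$q2.5_log10M <= esa$q25_log10M &
                    esa$q75_log10M <= esa$q97.5_log10M))
  # a series with a single step is rejected
  one_step <- tab[tab$step == 0, ]
  expect_error(estimate_standard_addition(fx$posterior, one_step),
               "insufficient design")
})
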