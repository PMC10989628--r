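# Shared (memoised) MCMC fixtures so expensive fits run once per test session.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

quick_settings <- function(seed, draws = 1000, warmup = 1000) {
  mcmc_settings(chains = 2, warmup = warmup, draws = draws, seed = seed)
}

# Default-scenario 4-electrode array, its calibration, and the joint fit.
cached_array_fit <- function() {
  memo_fixture("array_fit", function() {
    arr <- simulate_array(array_spec(), seed = 3)
    cal <- simulate_calibration(arr, calibration_design(), seed = 4)
    post <- fit_array(cal, settings = quick_settings(3))
    list(array = arr, calibration = cal, posterior = post)
  })
}

# Parameter-recovery study: 20 electrodes from the default scenario (five
# seeded 4-electrode arrays), each array fitted jointly; returns one row per
# electrode with truth, posterior medians and 95% intervals for S and logK.
cached_recovery_study <- function() {
  memo_fixture("recovery_study", function() {
    rows <- list()
    for (s in 11:15) {
      arr <- simulate_array(array_spec(), seed = s)
      cal <- simulate_calibration(arr, calibration_design(), seed = s + 50L)
      post <- fit_array(cal, settings = quick_settings(s))
      d <- diagnostics_report(post)
      for (i in seq_len(nrow(arr))) {
        id <- arr$electrode_id[i]
        ds <- d[d$electrode_id == id & d$parameter == "S", ]
        dk <- d[d$electrode_id == id & d$parameter == "logK", ]
        rows[[length(rows) + 1L]] <- data.frame(
          seed = s, electrode_id = id,
          S_true = arr$slope[i], S_median = ds$median,
          S_lo = ds$q2.5, S_hi = ds$q97.5,
          logK_true = log10(arr$K_bg[i]), logK_lo = dk$q2.5,
          logK_hi = dk$q97.5)
      }
    }
    do.call(rbind, rows)
  })
}
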