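# Concentration estimation from calibration posteriors: direct potentiometry
# (invert the fitted curve) and standard addition (fit the spike series with
# a free per-series baseline offset, so any E0 drift cancels). Estimation is
# per posterior draw: within each draw the concentration maximises the joint
# Normal likelihood of all electrodes' readings, electrodes weighted by
# 1/sigma^2 ("automatically weighting them based on individual precision");
# the draws of that maximiser are then summarised by the posterior median
# and central 50%/95% intervals. This plug-in scheme is an approximation to
# a full joint posterior; see the methods vignette.

#' Standard-addition schedule
#'
#' @param initial_volume_mL Initial sample volume V0 (> 0).
#' @param added_volume_mL Ordered spike volumes (mL, all > 0).
#' @param standard_conc_M Standard concentration per spike (mol/L, > 0);
#'   recycled if scalar.
#' @return An object of class `addition_schedule`.
#' @export
addition_schedule <- function(initial_volume_mL, added_volume_mL,
                              standard_conc_M) {
  stopifnot(initial_volume_mL > 0)
  if (length(added_volume_mL) > 0) {
    standard_conc_M <- rep_len(standard_conc_M, length(added_volume_mL))
    stopifnot(all(added_volume_mL > 0), all(standard_conc_M > 0))
  } else {
    standard_conc_M <- numeric(0)
  }
  structure(list(initial_volume_mL = initial_volume_mL,
                 added_volume_mL = as.numeric(added_volume_mL),
                 standard_conc_M = as.numeric(standard_conc_M)),
            class = "addition_schedule")
}

#' Volume-corrected concentration after k additions
#'
#' Total-mass / total-volume bookkeeping of standard addition:
#' `(c0*V0 + sum_{i<=k} c_std_i*V_i) / (V0 + sum_{i<=k} V_i)`; `k = 0`
#' returns `c0`.
#'
#' @param c0 Initial concentration (mol/L).
#' @param schedule An [addition_schedule()].
#' @param k Number of additions applied (0..length of schedule).
#' @return Concentration in the cell after the k-th addition (mol/L).
#' @export
volume_corrected_conc <- function(c0, schedule, k) {
  stopifnot(inherits(schedule, "addition_schedule"))
  k <- as.integer(k)
  if (k < 0 || k > length(schedule$added_volume_mL)) {
    stop("k outside the schedule", call. = FALSE)
  }
  if (k == 0L) return(c0)
  v <- schedule$added_volume_mL[seq_len(k)]
  cs <- schedule$standard_conc_M[seq_len(k)]
  (c0 * schedule$initial_volume_mL + sum(cs * v)) /
    (schedule$initial_volume_mL + sum(v))
}

# Cumulative added mass A_k and volume B_k for all steps 0..K, so the cell
# concentration is (c0*V0 + A_k)/(V0 + B_k); vectorised over draws later.
schedule_cumulants <- function(schedule) {
  v <- schedule$added_volume_mL
  cs <- schedule$standard_conc_M
  list(A = c(0, cumsum(cs * v)), B = c(0, cumsum(v)),
       V0 = schedule$initial_volume_mL)
}

#' Classical single-spike standard addition
#'
#' Closed-form inversion used as an independent oracle for the Bayesian
#' estimator: with one spike (V1, c_std) into V0 and emf change `dE`,
#' `c0 = c_std*V1 / ((V0+V1)*10^(dE/S) - V0)`. Assumes a negligible
#' background (pure Nernstian response).
#'
#' @param emf0,emf1 emf before and after the spike (mV).
#' @param slope Electrode slope S (mV/decade), non-zero.
#' @param schedule An [addition_schedule()] with exactly one step.
#' @return Estimated initial concentration c0 (mol/L).
#' @export
classical_standard_addition <- function(emf0, emf1, slope, schedule) {
  stopifnot(inherits(schedule, "addition_schedule"),
            length(schedule$added_volume_mL) == 1)
  if (!is.finite(slope) || slope == 0) {
    stop("degenerate slope", call. = FALSE)
  }
  v0 <- schedule$initial_volume_mL
  v1 <- schedule$added_volume_mL[1]
  cs <- schedule$standard_conc_M[1]
  denom <- (v0 + v1) * 10^((emf1 - emf0) / slope) - v0
  if (denom <= 0) {
    stop("inconsistent measurement: non-positive denominator", call. = FALSE)
  }
  cs * v1 / denom
}

# Vectorised golden-section minimisation: f maps a vector x (one entry per
# draw) to objective values; each draw keeps its own bracket.
golden_min_vec <- function(f, lower, upper, n, iter = 70) {
  gr <- (sqrt(5) - 1) / 2
  a <- rep_len(lower, n)
  b <- rep_len(upper, n)
  for (i in seq_len(iter)) {
    c1 <- b - gr * (b - a)
    d1 <- a + gr * (b - a)
    left <- f(c1) < f(d1)
    b <- ifelse(left, d1, b)
    a <- ifelse(left, a, c1)
  }
  (a + b) / 2
}

# Assemble, for a set of electrodes with readings, the per-draw matrices
# needed by the estimators. draws: ise_posterior; ids: electrode ids used.
draw_matrices <- function(draws, ids) {
  missing <- setdiff(ids, draws$electrodes)
  if (length(missing) > 0) {
    stop("no posterior draws for electrode(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(draws$draws[ids], function(d) {
    list(E0 = d$E0, S = d$S, K = 10^d$logK, sigma = d$sigma,
         w = 1 / pmax(d$sigma, 1e-6)^2)
  })
}

summarise_draws_log10 <- function(x, analyte, sample_id, censored_frac) {
  q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  ppm <- if (!is.null(analyte)) molar_to_ppm(10^q, analyte) else rep(NA_real_, 5)
  data.frame(sample_id = sample_id,
             est_log10M = q[3], q25_log10M = q[2], q75_log10M = q[4],
             q2.5_log10M = q[1], q97.5_log10M = q[5],
             est_ppm = ppm[3], q2.5_ppm = ppm[1], q97.5_ppm = ppm[5],
             width95_log10 = q[5] - q[1], width50_log10 = q[4] - q[2],
             censored = censored_frac > 0.5, censored_frac = censored_frac,
             stringsAsFactors = FALSE)
}

#' Direct-potentiometry concentration estimates
#'
#' For each sample and each posterior draw, the concentration estimate
#' maximises the joint Normal likelihood of the sample's readings given the
#' draw's electrode parameters (a single shared concentration; replicate
#' readings enter individually, electrodes weighted by 1/sigma^2). So that
#' the spread of the draws is a genuine posterior uncertainty, each draw
#' sees the readings perturbed by its own noise level -- and, when a
#' baseline-drift scale `drift_sd` is declared, by a drift offset shared
#' within each electrode-occasion. In the Nernstian (linear) limit this
#' samples the sample-concentration posterior under a flat log10 prior
#' exactly; with one electrode and one reading the maximiser is the
#' closed-form inversion `log10(10^((emf-E0)/S) - K_bg)`.
#'
#' Direct potentiometry cannot correct baseline drift, only budget for it:
#' a non-zero `drift_sd` widens the intervals accordingly. Standard addition
#' ([estimate_standard_addition()]) cancels the offset instead.
#'
#' Draws whose pooled likelihood is maximised at zero concentration (reading
#' at or below the blank response) are pinned at the draw's background
#' level, an upper-bound-style value; when more than half the draws are
#' pinned the sample is flagged `censored` (indistinguishable from
#' background) rather than erroring.
#'
#' @param draws An `ise_posterior` covering every electrode in
#'   `measurements`.
#' @param measurements Data frame with columns `sample_id`, `electrode_id`,
#'   `occasion`, `emf_mV` (the sample CSV schema).
#' @param analyte An [analyte_spec()] for ppm conversion (default: the one
#'   stored in the posterior).
#' @param drift_sd Declared baseline-drift scale (mV, >= 0); part of the
#'   uncertainty budget, default 0.
#' @param seed Seed for the per-draw perturbations (estimation is
#'   reproducible given the posterior and this seed).
#' @return Data frame of class `ise_estimates`: one row per sample with the
#'   posterior median and central 50%/95% intervals on the log10 molar
#'   scale, ppm equivalents, interval widths and censoring flags.
#' @export
estimate_direct <- function(draws, measurements, analyte = NULL,
                            drift_sd = 0, seed = 1L) {
  stopifnot(inherits(draws, "ise_posterior"), drift_sd >= 0,
            all(c("sample_id", "electrode_id", "emf_mV") %in% names(measurements)))
  if (is.null(analyte)) analyte <- draws$analyte
  if (!"occasion" %in% names(measurements)) measurements$occasion <- 1L
  n <- draws$n_draws
  out <- with_local_seed(seed, {
    lapply(split(measurements, measurements$sample_id), function(ms) {
      ids <- unique(ms$electrode_id)
      dm <- draw_matrices(draws, ids)
      # Per-draw perturbed readings: reading noise sigma_d per row, plus a
      # drift offset (sd drift_sd) shared within each electrode-occasion.
      pert <- vector("list", nrow(ms))
      for (g in split(seq_len(nrow(ms)), paste(ms$electrode_id, ms$occasion))) {
        sig <- dm[[ms$electrode_id[g[1]]]]$sigma
        dr <- stats::rnorm(n, 0, drift_sd)
        for (i in g) pert[[i]] <- ms$emf_mV[i] + dr + stats::rnorm(n, 0, sig)
      }
      # Gradient sign as conc -> 0: sum w S (emf - blank)/K per reading.
      grad0 <- rep(0, n)
      for (i in seq_len(nrow(ms))) {
        p <- dm[[ms$electrode_id[i]]]
        blank <- p$E0 + p$S * log10(p$K)
        grad0 <- grad0 + p$w * p$S * (pert[[i]] - blank) / p$K
      }
      cens <- grad0 <= 0

      obj <- function(x) {
        tot <- rep(0, n)
        for (i in seq_len(nrow(ms))) {
          p <- dm[[ms$electrode_id[i]]]
          mu <- p$E0 + p$S * log10(10^x + p$K)
          tot <- tot + p$w * (pert[[i]] - mu)^2
        }
        tot
      }
      xhat <- golden_min_vec(obj, -14, 2, n)
      if (any(cens)) {
        lk <- rowMeans(sapply(ids, function(id) log10(dm[[id]]$K)))
        xhat[cens] <- lk[cens]
      }
      summarise_draws_log10(xhat, analyte, ms$sample_id[1], mean(cens))
    })
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ise_estimates", "data.frame")
  out
}

#' Standard-addition concentration estimates
#'
#' Per posterior draw, the initial concentration `c0` maximises the joint
#' Normal likelihood of each electrode's spike series with a free baseline
#' offset per electrode-series: the offset is profiled out (series are
#' mean-centred per draw), so any occasion-specific E0 shift -- drift --
#' cancels exactly. Slope, background and noise come from the calibration
#' draws and are not re-estimated in-sample. As in [estimate_direct()], each
#' draw sees the series perturbed by its own reading noise, so the spread of
#' the draws reflects both calibration uncertainty and measurement noise; a
#' shared baseline offset would cancel, so no drift term is needed here.
#'
#' @param draws An `ise_posterior`.
#' @param measurements Standard-addition table: columns `sample_id`,
#'   `electrode_id`, `step`, `initial_volume_mL`, `added_volume_mL`,
#'   `standard_conc_M`, `emf_mV`; step 0 is the unspiked sample and every
#'   series needs >= 2 steps.
#' @param analyte An [analyte_spec()] for ppm conversion.
#' @param seed Seed for the per-draw perturbations.
#' @return Data frame of class `ise_estimates`, one row per sample.
#' @export
estimate_standard_addition <- function(draws, measurements, analyte = NULL,
                                       seed = 1L) {
  stopifnot(inherits(draws, "ise_posterior"),
            all(c("sample_id", "electrode_id", "step", "initial_volume_mL",
                  "added_volume_mL", "standard_conc_M", "emf_mV") %in%
                  names(measurements)))
  if (is.null(analyte)) analyte <- draws$analyte
  n <- draws$n_draws
  out <- with_local_seed(seed, {
    lapply(split(measurements, measurements$sample_id), function(ms) {
      steps <- sort(unique(ms$step))
      if (length(steps) < 2 || steps[1] != 0) {
        stop("insufficient design: standard addition needs steps 0..K (>= 2)",
             call. = FALSE)
      }
      add <- ms[ms$electrode_id == ms$electrode_id[1], ]
      add <- add[order(add$step), ]
      schedule <- addition_schedule(add$initial_volume_mL[1],
                                    add$added_volume_mL[add$step > 0],
                                    add$standard_conc_M[add$step > 0])
      cum <- schedule_cumulants(schedule)
      ids <- unique(ms$electrode_id)
      dm <- draw_matrices(draws, ids)

      series <- lapply(ids, function(id) {
        s <- ms[ms$electrode_id == id, ]
        s <- s[order(s$step), ]
        # perturbed series, centred per draw (profiles out E0 + offset)
        e <- matrix(rep(s$emf_mV, each = n), n) +
          matrix(stats::rnorm(n * length(s$emf_mV), 0, dm[[id]]$sigma), n)
        list(emf_c = e - rowMeans(e), k = s$step)
      })
      names(series) <- ids

      obj <- function(x) {
        c0 <- 10^x
        tot <- rep(0, n)
        for (id in ids) {
          p <- dm[[id]]
          sr <- series[[id]]
          kk <- sr$k + 1L
          # model emf per step: S * log10(conc_k + K); offset+E0 profiled out
          m <- matrix(0, n, length(kk))
          for (j in seq_along(kk)) {
            conc <- (c0 * cum$V0 + cum$A[kk[j]]) / (cum$V0 + cum$B[kk[j]])
            m[, j] <- p$S * log10(conc + p$K)
          }
          m <- m - rowMeans(m)
          tot <- tot + p$w * rowSums((sr$emf_c - m)^2)
        }
        tot
      }
      xhat <- golden_min_vec(obj, -12, 1, n)
      summarise_draws_log10(xhat, analyte, ms$sample_id[1], 0)
    })
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ise_estimates", "data.frame")
  out
}
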