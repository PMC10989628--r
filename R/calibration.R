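# Bayesian nonlinear calibration of the Nikolsky-Eisenman response:
#   emf_ij ~ Normal(E0_j + S_j * log10(10^x_ij + 10^logK_j), sigma_j)
# fitted per electrode, jointly for arrays (independent parameters per
# electrode, sampled in one model), via JAGS. The background is
# parameterised as log10 K_bg for positivity; the noise sd gets a
# half-Cauchy prior.

# Sampling is on Ec (curve height at the centre xbar of the calibration
# range) rather than E0 directly: Ec and S are nearly uncorrelated a
# posteriori, which lets JAGS's one-parameter samplers mix well. E0 is the
# derived intercept; its weakly-informative Normal prior is placed on Ec
# (equivalent up to the fixed shift S*xbar at these prior scales).
ise_jags_model <- "
model {
  for (i in 1:N) {
    mu[i] <- Ec[el[i]] + S[el[i]] * (log(pow(10, x[i]) + pow(10, logK[el[i]])) / 2.302585092994046 - xbar[el[i]])
    y[i] ~ dnorm(mu[i], tau[el[i]])
  }
  for (j in 1:J) {
    Ec[j] ~ dnorm(E0_mean[j], E0_prec)
    S[j] ~ dnorm(S_mean, S_prec)
    logK[j] ~ dunif(logK_lo[j], logK_hi[j])
    sigma[j] ~ dt(0, sig_prec, 1) T(0.001,)
    tau[j] <- pow(sigma[j], -2)
    E0[j] <- Ec[j] - S[j] * xbar[j]
  }
}
"

#' Prior specification for calibration
#'
#' Weakly informative defaults: E0 ~ Normal(mean of the electrode's observed
#' emf, 1000 mV), slope ~ Normal(theoretical Nernstian slope, 10 mV/decade),
#' log10 K_bg ~ Uniform(lowest calibration step - 3, highest step),
#' sigma ~ half-Cauchy(2 mV) truncated below at 0.001 mV (a negligible
#' physical floor that keeps the posterior proper for noise-free data).
#' `NULL` fields are resolved from the data and analyte at fit time.
#'
#' @param E0_mean,E0_sd Normal prior on the standard potential (mV).
#' @param slope_mean,slope_sd Normal prior on the slope (mV/decade).
#' @param logK_lower,logK_upper Uniform prior bounds on log10 K_bg.
#' @param sigma_scale Half-Cauchy scale for the noise sd (mV).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(E0_mean = NULL, E0_sd = 1000,
                       slope_mean = NULL, slope_sd = 10,
                       logK_lower = NULL, logK_upper = NULL,
                       sigma_scale = 2) {
  stopifnot(E0_sd > 0, slope_sd > 0, sigma_scale > 0)
  if (!is.null(logK_lower) && !is.null(logK_upper) &&
      logK_lower >= logK_upper) {
    stop("logK prior bounds must be ordered", call. = FALSE)
  }
  structure(list(E0_mean = E0_mean, E0_sd = E0_sd,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 logK_lower = logK_lower, logK_upper = logK_upper,
                 sigma_scale = sigma_scale),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param chains Number of chains (>= 2).
#' @param warmup Adaptation + burn-in iterations per chain.
#' @param draws Retained draws per chain (>= 1000).
#' @param seed Integer seed for the samplers.
#' @param rhat_threshold Convergence gate on split R-hat (default 1.05).
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 2, warmup = 1000, draws = 1000, seed = 1,
                          rhat_threshold = 1.05) {
  stopifnot(chains >= 2, draws >= 1000, warmup >= 0, rhat_threshold >= 1.0)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold),
            class = "mcmc_settings")
}

# Validate one electrode's calibration data frame (log10_conc, emf_mV).
check_calibration_data <- function(d, id) {
  if (nrow(d) < 4) {
    stop("calibration for ", id, " needs >= 4 records", call. = FALSE)
  }
  if (any(!is.finite(d$log10_conc)) || any(!is.finite(d$emf_mV))) {
    stop("calibration for ", id, " has non-finite values", call. = FALSE)
  }
  if (diff(range(d$log10_conc)) < 2) {
    stop("calibration for ", id, " must span >= 2 decades", call. = FALSE)
  }
  if (stats::sd(d$emf_mV) == 0) {
    stop("degenerate calibration for ", id, ": all emf equal", call. = FALSE)
  }
  invisible(TRUE)
}

split_rhat <- function(mat) {
  # mat: iterations x chains. Split each chain in half -> 2*chains sequences.
  n <- nrow(mat) %/% 2
  if (n < 2) return(NA_real_)
  halves <- cbind(mat[seq_len(n), , drop = FALSE],
                  mat[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Run one JAGS fit over a list of per-electrode data frames.
run_jags_fit <- function(datasets, priors, settings, analyte, warmup) {
  ids <- names(datasets)
  J <- length(datasets)
  x <- unlist(lapply(datasets, function(d) d$log10_conc), use.names = FALSE)
  y <- unlist(lapply(datasets, function(d) d$emf_mV), use.names = FALSE)
  el <- rep(seq_len(J), vapply(datasets, nrow, integer(1)))

  s_mean <- priors$slope_mean
  if (is.null(s_mean)) s_mean <- theoretical_slope(analyte)
  e0_mean <- priors$E0_mean
  if (is.null(e0_mean)) {
    e0_mean <- vapply(datasets, function(d) mean(d$emf_mV), numeric(1))
  }
  e0_mean <- rep_len(e0_mean, J)
  lo <- priors$logK_lower
  hi <- priors$logK_upper
  lo_j <- vapply(datasets, function(d)
    if (is.null(lo)) min(d$log10_conc) - 3 else lo, numeric(1))
  hi_j <- vapply(datasets, function(d)
    if (is.null(hi)) max(d$log10_conc) else hi, numeric(1))

  xbar <- vapply(datasets, function(d) mean(d$log10_conc), numeric(1))
  data <- list(N = length(y), J = J, x = x, y = y, el = el, xbar = xbar,
               E0_mean = e0_mean, E0_prec = 1 / priors$E0_sd^2,
               S_mean = s_mean, S_prec = 1 / priors$slope_sd^2,
               logK_lo = lo_j, logK_hi = hi_j,
               sig_prec = 1 / priors$sigma_scale^2)

  inits <- lapply(seq_len(settings$chains), function(ch) {
    jit <- (ch - 1) / settings$chains
    list(Ec = e0_mean + 2 * jit, S = rep(s_mean * (1 + 0.02 * jit), J),
         logK = lo_j + (0.4 + 0.2 * jit) * (hi_j - lo_j),
         sigma = rep(1 + jit, J),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = settings$seed + 1000L * ch)
  })

  model <- rjags::jags.model(textConnection(ise_jags_model), data = data,
                             inits = inits, n.chains = settings$chains,
                             n.adapt = max(100L, warmup %/% 2L),
                             quiet = TRUE)
  stats::update(model, n.iter = warmup, progress.bar = "none")
  samp <- rjags::coda.samples(model, c("E0", "S", "logK", "sigma"),
                              n.iter = settings$draws, progress.bar = "none")
  list(samples = samp, ids = ids, J = J)
}

# Reshape coda output into per-electrode draw matrices + diagnostics.
collect_posterior <- function(fit, priors, settings, analyte) {
  samp <- fit$samples
  J <- fit$J
  vname <- function(base, j) if (J == 1) base else sprintf("%s[%d]", base, j)
  draws <- list()
  diag_rows <- list()
  for (j in seq_len(J)) {
    id <- fit$ids[j]
    mats <- lapply(c(E0 = "E0", S = "S", logK = "logK", sigma = "sigma"),
                   function(b) {
                     sapply(samp, function(ch) as.numeric(ch[, vname(b, j)]))
                   })
    flat <- data.frame(E0 = as.numeric(mats$E0), S = as.numeric(mats$S),
                       logK = as.numeric(mats$logK),
                       sigma = as.numeric(mats$sigma))
    draws[[id]] <- flat
    for (p in names(mats)) {
      v <- as.numeric(mats[[p]])
      ess <- tryCatch(as.numeric(coda::effectiveSize(v)),
                      error = function(e) NA_real_)
      q <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        electrode_id = id, parameter = p, rhat = split_rhat(mats[[p]]),
        ess = ess, median = q[3], q25 = q[2], q75 = q[4],
        q2.5 = q[1], q97.5 = q[5], stringsAsFactors = FALSE)
    }
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  new_ise_posterior(draws, diagnostics = diagnostics,
                    n_chains = settings$chains, priors = priors,
                    settings = settings, analyte = analyte)
}

#' Construct a posterior-draws object
#'
#' Container for joint posterior samples of all electrode parameters. Mostly
#' produced by [fit_array()]/[fit_single()]; building one directly (e.g. a
#' degenerate posterior concentrated at known parameters) is useful for
#' testing estimators against closed forms.
#'
#' @param draws Named list (one element per electrode) of data frames with
#'   columns `E0`, `S`, `logK`, `sigma`, all with the same number of rows
#'   (draws are aligned across electrodes).
#' @param diagnostics Optional per-parameter diagnostics table.
#' @param n_chains Number of chains the draws came from.
#' @param priors,settings,analyte Provenance, stored as-is.
#' @return An object of class `ise_posterior`.
#' @export
new_ise_posterior <- function(draws, diagnostics = NULL, n_chains = 1,
                              priors = NULL, settings = NULL, analyte = NULL) {
  stopifnot(is.list(draws), length(draws) >= 1, !is.null(names(draws)))
  n <- unique(vapply(draws, nrow, integer(1)))
  if (length(n) != 1) stop("draws must be aligned across electrodes", call. = FALSE)
  for (d in draws) {
    stopifnot(all(c("E0", "S", "logK", "sigma") %in% names(d)))
    if (any(!is.finite(as.matrix(d[, c("E0", "S", "logK", "sigma")])))) {
      stop("posterior draws must be finite", call. = FALSE)
    }
    if (any(d$sigma < 0)) stop("sigma draws must be >= 0", call. = FALSE)
  }
  structure(list(electrodes = names(draws), draws = draws, n_draws = n,
                 n_chains = n_chains, diagnostics = diagnostics,
                 priors = priors, settings = settings, analyte = analyte),
            class = "ise_posterior")
}

#' Degenerate posterior at known parameters
#'
#' All draws equal to the supplied parameter values; used to check
#' estimators against closed-form oracles.
#'
#' @param params An [electrode_params()] or `ise_array` data frame.
#' @param n_draws Number of (identical) draws.
#' @return An `ise_posterior`.
#' @export
degenerate_posterior <- function(params, n_draws = 200) {
  arr <- as_array_df(params)
  draws <- lapply(seq_len(nrow(arr)), function(i) {
    data.frame(E0 = rep(arr$E0[i], n_draws), S = rep(arr$slope[i], n_draws),
               logK = rep(log10(pmax(arr$K_bg[i], 1e-300)), n_draws),
               sigma = rep(arr$sigma[i], n_draws))
  })
  names(draws) <- arr$electrode_id
  new_ise_posterior(draws)
}

#' Fit the calibration model to an electrode array
#'
#' Joint MCMC fit of (E0, S, log10 K_bg, sigma) for each electrode, with
#' independent parameters per electrode, so downstream sample estimation can
#' pool all electrodes' likelihoods draw by draw. Convergence is gated on
#' split R-hat: if any parameter exceeds the threshold the fit is retried
#' once with doubled warmup, and a diagnostic error carrying the R-hat table
#' is raised if that also fails.
#'
#' @param datasets Calibration data: either one data frame with columns
#'   `electrode_id`, `log10_conc`, `emf_mV`, or a named list of per-electrode
#'   data frames (`log10_conc`, `emf_mV`).
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @param analyte An [analyte_spec()]; sets the slope prior mean (and its
#'   sign) when the prior does not fix it.
#' @return An `ise_posterior`.
#' @export
fit_array <- function(datasets, priors = prior_spec(),
                      settings = mcmc_settings(), analyte = analyte_nh4()) {
  stopifnot(inherits(priors, "prior_spec"), inherits(settings, "mcmc_settings"),
            inherits(analyte, "analyte_spec"))
  if (is.data.frame(datasets)) {
    stopifnot(all(c("electrode_id", "log10_conc", "emf_mV") %in% names(datasets)))
    datasets <- split(datasets[, c("log10_conc", "emf_mV")],
                      datasets$electrode_id)
  }
  if (length(datasets) < 1) stop("need >= 1 calibration dataset", call. = FALSE)
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- paste0("ISE", seq_along(datasets))
  }
  for (id in names(datasets)) check_calibration_data(datasets[[id]], id)

  warmup <- settings$warmup
  for (attempt in 1:2) {
    fit <- run_jags_fit(datasets, priors, settings, analyte, warmup)
    post <- collect_posterior(fit, priors, settings, analyte)
    rh <- post$diagnostics$rhat
    ok <- all(is.na(rh) | rh <= settings$rhat_threshold)
    if (ok) return(post)
    warmup <- warmup * 2L
  }
  bad <- post$diagnostics[!is.na(post$diagnostics$rhat) &
                            post$diagnostics$rhat > settings$rhat_threshold, ]
  cond <- structure(
    class = c("ise_convergence_error", "error", "condition"),
    list(message = paste0("calibration did not converge (max R-hat ",
                          format(max(bad$rhat), digits = 4),
                          ") after retry with doubled warmup"),
         call = sys.call(-1), diagnostics = bad))
  stop(cond)
}

#' Fit a single electrode
#'
#' Reduction of [fit_array()] to one electrode.
#'
#' @param data Data frame with columns `log10_conc`, `emf_mV` (an
#'   `electrode_id` column is honoured if present).
#' @inheritParams fit_array
#' @return An `ise_posterior` with one electrode.
#' @export
fit_single <- function(data, priors = prior_spec(), settings = mcmc_settings(),
                       analyte = analyte_nh4()) {
  id <- if ("electrode_id" %in% names(data)) as.character(data$electrode_id[1]) else "ISE1"
  l <- list(data[, c("log10_conc", "emf_mV")])
  names(l) <- id
  fit_array(l, priors = priors, settings = settings, analyte = analyte)
}

#' Diagnostics summary of a posterior
#'
#' Per-parameter split R-hat, effective sample size, posterior median and
#' central 50%/95% intervals. Zero-variance (constant) chains yield `NA`
#' R-hat rather than an error.
#'
#' @param draws An `ise_posterior`.
#' @return Data frame with one row per electrode x parameter.
#' @export
diagnostics_report <- function(draws) {
  stopifnot(inherits(draws, "ise_posterior"))
  if (!is.null(draws$diagnostics)) return(draws$diagnostics)
  # Posterior built directly from draws: treat draws as a single chain.
  rows <- list()
  for (id in draws$electrodes) {
    d <- draws$draws[[id]]
    for (p in c("E0", "S", "logK", "sigma")) {
      v <- d[[p]]
      q <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
      ess <- tryCatch(as.numeric(coda::effectiveSize(v)),
                      error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        electrode_id = id, parameter = p,
        rhat = split_rhat(matrix(v, ncol = 1)), ess = ess,
        median = q[3], q25 = q[2], q75 = q[4], q2.5 = q[1], q97.5 = q[5],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ise_posterior <- function(x, ...) {
  cat("ISE calibration posterior:", length(x$electrodes), "electrode(s),",
      x$n_draws, "draws x", x$n_chains, "chain(s)\n")
  print(diagnostics_report(x), digits = 4)
  invisible(x)
}
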