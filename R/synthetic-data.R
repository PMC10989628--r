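# Synthetic-data generators: electrode arrays, calibration series, drifting
# sample emf readings, standard-addition series and paired method-comparison
# tables. Every generator is a pure function of (spec, seed): the RNG state
# is saved and restored around each call, so generators never disturb (or
# depend on) the caller's RNG stream.

# Run expr under a local, seeded Mersenne-Twister stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) {
    stop("a finite integer seed is required", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Electrode-array specification
#'
#' Population from which individual electrode parameters are drawn. The
#' defaults describe the working scenario used throughout this package: four
#' slightly sub-Nernstian electrodes (slope 57 +/- 2 mV/decade), standard
#' potentials 200 +/- 5 mV, a fixed interference background of 10^-5.5 mol/L
#' and 1 mV Gaussian emf noise -- numbers that put the detection limits in
#' the 10^-6 to 10^-5 mol/L range typical of nitrate/ammonium ISEs.
#'
#' @param n_electrodes Number of electrodes (>= 1).
#' @param E0_mean,E0_sd Standard-potential population mean and sd (mV).
#' @param slope_mean,slope_sd Slope population mean and sd (mV/decade).
#' @param log10Kbg_mean,log10Kbg_sd Population mean and sd of the log10
#'   interference background (mol/L).
#' @param noise_sd emf noise sd per reading (mV).
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(n_electrodes = 4, E0_mean = 200, E0_sd = 5,
                       slope_mean = 57, slope_sd = 2,
                       log10Kbg_mean = -5.5, log10Kbg_sd = 0,
                       noise_sd = 1) {
  stopifnot(n_electrodes >= 1,
            E0_sd >= 0, slope_sd >= 0, log10Kbg_sd >= 0, noise_sd >= 0)
  structure(
    list(n_electrodes = as.integer(n_electrodes),
         E0_mean = E0_mean, E0_sd = E0_sd,
         slope_mean = slope_mean, slope_sd = slope_sd,
         log10Kbg_mean = log10Kbg_mean, log10Kbg_sd = log10Kbg_sd,
         noise_sd = noise_sd),
    class = "array_spec"
  )
}

#' Drift model for sample measurements
#'
#' Baseline (E0) drift between measurement occasions. `occasion_offset` adds
#' an independent Normal(0, occasion_sd) offset per electrode and occasion;
#' `linear` adds `rate * t` with `t` the occasion time in hours; `none`
#' leaves the baseline untouched.
#'
#' @param kind One of `"none"`, `"occasion_offset"`, `"linear"`.
#' @param occasion_sd Offset sd in mV (>= 0), used by `occasion_offset`.
#' @param rate Drift rate in mV/h, used by `linear`.
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(kind = c("none", "occasion_offset", "linear"),
                        occasion_sd = 10, rate = 0) {
  kind <- match.arg(kind)
  stopifnot(occasion_sd >= 0)
  structure(list(kind = kind, occasion_sd = occasion_sd, rate = rate),
            class = "drift_model")
}

#' Calibration design
#'
#' @param log10_conc_steps Strictly increasing log10 concentration steps
#'   (mol/L); at least 3. Default: 9 half-decade steps from 1e-6 to 1e-2 M.
#' @param replicates Readings per step (>= 1).
#' @return An object of class `calibration_design`.
#' @export
calibration_design <- function(log10_conc_steps = seq(-6, -2, by = 0.5),
                               replicates = 1) {
  if (length(log10_conc_steps) < 3 || any(diff(log10_conc_steps) <= 0)) {
    stop("need >= 3 strictly increasing concentration steps", call. = FALSE)
  }
  stopifnot(replicates >= 1)
  structure(list(log10_conc_steps = log10_conc_steps,
                 replicates = as.integer(replicates)),
            class = "calibration_design")
}

#' Method-comparison scenario
#'
#' Paired concentration tables: per sample, each method reports
#' `truth * recovery * (1 + eps)` with `eps ~ Normal(0, cv)`. Emulates the
#' structure of extractant-comparison and ISE-vs-reference tables.
#'
#' @param n_samples Number of paired samples.
#' @param log10_conc_range Log-uniform bounds for true concentrations
#'   (log10 mol/L).
#' @param recovery_A,recovery_B Fractional recoveries in (0, 1.5].
#' @param measurement_cv Relative measurement noise (>= 0).
#' @param analyte An [analyte_spec()] used to express values in ppm.
#' @param method_A,method_B Method labels.
#' @return An object of class `comparison_scenario`.
#' @export
comparison_scenario <- function(n_samples = 11,
                                log10_conc_range = c(-5, -3),
                                recovery_A = 1.0, recovery_B = 0.98,
                                measurement_cv = 0.05,
                                analyte = analyte_no3(),
                                method_A = "KCl", method_B = "MgSO4") {
  stopifnot(n_samples >= 1, length(log10_conc_range) == 2,
            recovery_A > 0, recovery_A <= 1.5,
            recovery_B > 0, recovery_B <= 1.5,
            measurement_cv >= 0)
  structure(
    list(n_samples = as.integer(n_samples),
         log10_conc_range = log10_conc_range,
         recovery_A = recovery_A, recovery_B = recovery_B,
         measurement_cv = measurement_cv, analyte = analyte,
         method_A = method_A, method_B = method_B),
    class = "comparison_scenario"
  )
}

#' Draw an electrode array
#'
#' Draws per-electrode parameters from the population described by an
#' [array_spec()]: E0 ~ Normal(E0_mean, E0_sd), slope ~ Normal(slope_mean,
#' slope_sd), log10 K_bg ~ Normal(log10Kbg_mean, log10Kbg_sd); the noise sd
#' is shared.
#'
#' @param spec An [array_spec()].
#' @param seed Integer seed (mandatory).
#' @return A data frame of class `ise_array` with columns `electrode_id`,
#'   `E0`, `slope`, `K_bg`, `sigma`.
#' @export
simulate_array <- function(spec = array_spec(), seed) {
  stopifnot(inherits(spec, "array_spec"))
  with_local_seed(seed, {
    n <- spec$n_electrodes
    out <- data.frame(
      electrode_id = paste0("ISE", seq_len(n)),
      E0 = stats::rnorm(n, spec$E0_mean, spec$E0_sd),
      slope = stats::rnorm(n, spec$slope_mean, spec$slope_sd),
      K_bg = 10^stats::rnorm(n, spec$log10Kbg_mean, spec$log10Kbg_sd),
      sigma = rep(spec$noise_sd, n),
      stringsAsFactors = FALSE
    )
    class(out) <- c("ise_array", "data.frame")
    out
  })
}

# Coerce an electrode_params or ise_array to the common data-frame form.
as_array_df <- function(params) {
  if (inherits(params, "electrode_params")) {
    out <- data.frame(electrode_id = params$electrode_id, E0 = params$E0,
                      slope = params$slope, K_bg = params$K_bg,
                      sigma = params$sigma, stringsAsFactors = FALSE)
  } else if (is.data.frame(params)) {
    need <- c("electrode_id", "E0", "slope", "K_bg", "sigma")
    if (!all(need %in% names(params))) {
      stop("array data frame must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    out <- as.data.frame(params)[, need]
  } else {
    stop("params must be electrode_params or an ise_array", call. = FALSE)
  }
  out
}

row_params <- function(df, i) {
  electrode_params(E0 = df$E0[i], slope = df$slope[i], K_bg = df$K_bg[i],
                   sigma = df$sigma[i], electrode_id = df$electrode_id[i])
}

#' Simulate a calibration series
#'
#' emf readings at known concentration steps:
#' `emf = nikolsky_emf(params, 10^step) + Normal(0, sigma)`.
#'
#' @param params An [electrode_params()] or an `ise_array` data frame.
#' @param design A [calibration_design()].
#' @param seed Integer seed.
#' @return Data frame with columns `electrode_id`, `log10_conc`, `emf_mV`.
#' @export
simulate_calibration <- function(params, design = calibration_design(), seed) {
  stopifnot(inherits(design, "calibration_design"))
  arr <- as_array_df(params)
  with_local_seed(seed, {
    steps <- rep(design$log10_conc_steps, each = design$replicates)
    out <- do.call(rbind, lapply(seq_len(nrow(arr)), function(i) {
      p <- row_params(arr, i)
      mu <- nikolsky_emf(p, 10^steps)
      data.frame(electrode_id = p$electrode_id, log10_conc = steps,
                 emf_mV = mu + stats::rnorm(length(mu), 0, p$sigma),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

# Drift offsets for n occasions of one electrode.
drift_offsets <- function(drift, n, t_hours) {
  switch(drift$kind,
         none = rep(0, n),
         occasion_offset = stats::rnorm(n, 0, drift$occasion_sd),
         linear = drift$rate * t_hours)
}

#' Simulate sample emf readings under drift
#'
#' One reading per electrode and sample occasion. Each electrode receives its
#' own occasion offset (baselines of different electrodes drift
#' independently): `emf = (E0 + delta_t) + S * log10(c_t + K_bg) + noise`.
#'
#' @param params An [electrode_params()] or an `ise_array` data frame.
#' @param drift A [drift_model()].
#' @param true_conc Vector of true sample concentrations (mol/L, > 0); one
#'   occasion per sample.
#' @param seed Integer seed.
#' @param t_hours Occasion times in hours for linear drift (default the
#'   occasion index).
#' @param sample_ids Optional sample labels.
#' @return Data frame with columns `sample_id`, `electrode_id`, `occasion`,
#'   `emf_mV`, plus the hidden truth in `true_conc` (dropped on write).
#' @export
simulate_sample_emfs <- function(params, drift = drift_model(), true_conc,
                                 seed, t_hours = seq_along(true_conc),
                                 sample_ids = NULL) {
  stopifnot(inherits(drift, "drift_model"), all(true_conc > 0))
  arr <- as_array_df(params)
  n <- length(true_conc)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n))
  with_local_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(arr)), function(i) {
      p <- row_params(arr, i)
      delta <- drift_offsets(drift, n, t_hours)
      mu <- p$E0 + delta + p$slope * log10(true_conc + p$K_bg)
      data.frame(sample_id = sample_ids, electrode_id = p$electrode_id,
                 occasion = seq_len(n),
                 emf_mV = mu + stats::rnorm(n, 0, p$sigma),
                 true_conc = true_conc, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a standard-addition series
#'
#' emf of one sample before and after each spike of standard. The occasion's
#' baseline offset is drawn once per electrode and shared by every step of
#' that electrode's series, so it cancels in emf differences -- the property
#' standard addition exploits.
#'
#' @param params An [electrode_params()] or an `ise_array` data frame.
#' @param schedule An [addition_schedule()].
#' @param c0 True initial sample concentration (mol/L, > 0).
#' @param drift A [drift_model()].
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @param t_hours Occasion time (h) for linear drift.
#' @return Data frame with columns `sample_id`, `electrode_id`, `step`,
#'   `initial_volume_mL`, `added_volume_mL`, `standard_conc_M`, `emf_mV`.
#'   Step 0 is the unspiked sample.
#' @export
simulate_standard_addition <- function(params, schedule, c0,
                                       drift = drift_model(), seed,
                                       sample_id = "S01", t_hours = 1) {
  stopifnot(inherits(schedule, "addition_schedule"),
            inherits(drift, "drift_model"), c0 > 0)
  arr <- as_array_df(params)
  k_max <- length(schedule$added_volume_mL)
  conc <- vapply(0:k_max, function(k) volume_corrected_conc(c0, schedule, k),
                 numeric(1))
  with_local_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(arr)), function(i) {
      p <- row_params(arr, i)
      delta <- drift_offsets(drift, 1, t_hours)
      mu <- p$E0 + delta + p$slope * log10(conc + p$K_bg)
      data.frame(sample_id = sample_id, electrode_id = p$electrode_id,
                 step = 0:k_max,
                 initial_volume_mL = schedule$initial_volume_mL,
                 added_volume_mL = c(0, schedule$added_volume_mL),
                 standard_conc_M = c(0, schedule$standard_conc_M),
                 emf_mV = mu + stats::rnorm(k_max + 1, 0, p$sigma),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate standard-addition series for several samples
#'
#' @param params Electrode array.
#' @param schedule An [addition_schedule()] shared by all samples.
#' @param c0 Vector of true initial concentrations.
#' @param drift A [drift_model()].
#' @param seed Integer seed.
#' @param sample_ids Optional labels.
#' @return Row-bound standard-addition table (see
#'   [simulate_standard_addition()]) with a `true_conc` column.
#' @export
simulate_sa_table <- function(params, schedule, c0, drift = drift_model(),
                              seed, sample_ids = NULL) {
  n <- length(c0)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n))
  out <- do.call(rbind, lapply(seq_len(n), function(s) {
    tab <- simulate_standard_addition(params, schedule, c0[s], drift,
                                      seed = seed + s, sample_id = sample_ids[s],
                                      t_hours = s)
    tab$true_conc <- c0[s]
    tab
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a paired method-comparison table
#'
#' @param scn A [comparison_scenario()].
#' @param seed Integer seed.
#' @return Data frame in the long comparison schema: `sample_id`, `analyte`,
#'   `method`, `conc_ppm` (two rows per sample), with the hidden truth in
#'   `true_ppm`.
#' @export
simulate_comparison_table <- function(scn = comparison_scenario(), seed) {
  stopifnot(inherits(scn, "comparison_scenario"))
  with_local_seed(seed, {
    n <- scn$n_samples
    lo <- scn$log10_conc_range[1]; hi <- scn$log10_conc_range[2]
    truth_molar <- 10^seq(lo, hi, length.out = n)
    truth_ppm <- molar_to_ppm(truth_molar, scn$analyte)
    a <- truth_ppm * scn$recovery_A *
      (1 + stats::rnorm(n, 0, scn$measurement_cv))
    b <- truth_ppm * scn$recovery_B *
      (1 + stats::rnorm(n, 0, scn$measurement_cv))
    ids <- sprintf("S%02d", seq_len(n))
    out <- rbind(
      data.frame(sample_id = ids, analyte = scn$analyte$name,
                 method = scn$method_A, conc_ppm = a, true_ppm = truth_ppm,
                 stringsAsFactors = FALSE),
      data.frame(sample_id = ids, analyte = scn$analyte$name,
                 method = scn$method_B, conc_ppm = b, true_ppm = truth_ppm,
                 stringsAsFactors = FALSE)
    )
    rownames(out) <- NULL
    out
  })
}

#' Pivot a long comparison table to paired columns
#'
#' @param tab Long comparison table (columns `sample_id`, `method`,
#'   `conc_ppm`).
#' @param method_A,method_B Which method goes in which column; defaults to
#'   the first two methods present.
#' @return Data frame with columns `sample_id`, `value_A`, `value_B` and
#'   attributes `method_A`, `method_B`.
#' @export
pair_comparison <- function(tab, method_A = NULL, method_B = NULL) {
  methods <- unique(tab$method)
  if (is.null(method_A)) method_A <- methods[1]
  if (is.null(method_B)) method_B <- methods[2]
  a <- tab[tab$method == method_A, c("sample_id", "conc_ppm")]
  b <- tab[tab$method == method_B, c("sample_id", "conc_ppm")]
  out <- merge(a, b, by = "sample_id", suffixes = c("_A", "_B"))
  names(out) <- c("sample_id", "value_A", "value_B")
  out <- out[order(out$sample_id), ]
  rownames(out) <- NULL
  attr(out, "method_A") <- method_A
  attr(out, "method_B") <- method_B
  out
}
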