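# Detection limits from the calibration posterior. Three notions:
#   * LOD_1969 -- the classical IUPAC ISE limit: intersection of the
#     extrapolated Nernstian line and the flat blank response, which for the
#     Nikolsky-Eisenman curve is exactly the background level K_bg.
#   * traditional LOQ -- one order of magnitude above LOD_1969.
#   * Bayesian LOD -- a detection-theoretic limit: the smallest
#     concentration whose mean response is distinguishable from the blank
#     with false-positive rate alpha and false-negative rate beta under the
#     draw's noise level. All are computed per posterior draw and summarised
#     by the median and central 95% interval, so each limit carries its own
#     uncertainty.

#' Detection-limit specification
#'
#' @param alpha False-positive rate in (0, 0.5).
#' @param beta False-negative rate in (0, 0.5).
#' @param unit Reporting unit, `"molar"` or `"ppm"`.
#' @return An object of class `lod_spec`.
#' @export
lod_spec <- function(alpha = 0.05, beta = 0.05, unit = c("molar", "ppm")) {
  stopifnot(alpha > 0, alpha < 0.5, beta > 0, beta < 0.5)
  structure(list(alpha = alpha, beta = beta, unit = match.arg(unit)),
            class = "lod_spec")
}

lod_summary <- function(per_draw, analyte, label, n_skipped = 0) {
  q <- stats::quantile(per_draw, c(0.025, 0.5, 0.975), names = FALSE)
  out <- data.frame(limit = label, median_M = q[2], q2.5_M = q[1],
                    q97.5_M = q[3], stringsAsFactors = FALSE)
  if (!is.null(analyte)) {
    out$median_ppm <- molar_to_ppm(q[2], analyte)
    out$q2.5_ppm <- molar_to_ppm(q[1], analyte)
    out$q97.5_ppm <- molar_to_ppm(q[3], analyte)
  }
  attr(out, "per_draw") <- per_draw
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Classical IUPAC detection limit (LOD 1969)
#'
#' Per draw, the intersection of the Nernstian asymptote
#' `E0 + S*log10(a)` with the blank line `E0 + S*log10(K_bg)` lies exactly
#' at `a = K_bg`, so the classical limit equals the fitted background.
#'
#' @param draws An `ise_posterior`.
#' @param electrode_id Electrode to report (default: first).
#' @param analyte An [analyte_spec()] for ppm conversion.
#' @return One-row data frame with the posterior median and 95% interval of
#'   the limit, in mol/L (and ppm when an analyte is known); the per-draw
#'   values are attached as attribute `per_draw`.
#' @export
lod_iupac <- function(draws, electrode_id = NULL, analyte = NULL) {
  stopifnot(inherits(draws, "ise_posterior"))
  if (is.null(analyte)) analyte <- draws$analyte
  if (is.null(electrode_id)) electrode_id <- draws$electrodes[1]
  d <- draws$draws[[electrode_id]]
  lod_summary(10^d$logK, analyte, "LOD_1969")
}

#' Traditional limit of quantification
#'
#' Ten times the detection limit, in whatever unit the limit is supplied.
#'
#' @param lod Detection limit (> 0), molar or ppm.
#' @return `10 * lod`.
#' @export
loq_traditional <- function(lod) {
  if (any(!is.finite(lod)) || any(lod <= 0)) stop("lod must be > 0", call. = FALSE)
  10 * lod
}

#' Bayesian detection limit
#'
#' Per draw, the smallest concentration whose mean response exceeds the
#' blank by enough to keep both error rates at (alpha, beta) under
#' Normal(0, sigma) noise:
#' `LOD = K_bg * (10^((z_{1-alpha} + z_{1-beta}) * sigma / |S|) - 1)`.
#' Draws with |S| below 1e-6 mV/decade are skipped (with a count); more than
#' 10% skipped raises a diagnostic error.
#'
#' @param draws An `ise_posterior`.
#' @param spec An [lod_spec()].
#' @param electrode_id Electrode to report (default: first).
#' @param analyte An [analyte_spec()] for ppm conversion.
#' @return As [lod_iupac()]; attribute `n_skipped` counts skipped draws.
#' @export
lod_bayesian <- function(draws, spec = lod_spec(), electrode_id = NULL,
                         analyte = NULL) {
  stopifnot(inherits(draws, "ise_posterior"), inherits(spec, "lod_spec"))
  if (is.null(analyte)) analyte <- draws$analyte
  if (is.null(electrode_id)) electrode_id <- draws$electrodes[1]
  d <- draws$draws[[electrode_id]]
  ok <- abs(d$S) > 1e-6
  n_skipped <- sum(!ok)
  if (n_skipped > 0.1 * nrow(d)) {
    stop("more than 10% of draws have a degenerate slope", call. = FALSE)
  }
  z <- stats::qnorm(1 - spec$alpha) + stats::qnorm(1 - spec$beta)
  per_draw <- 10^d$logK[ok] * (10^(z * d$sigma[ok] / abs(d$S[ok])) - 1)
  lod_summary(per_draw, analyte, "LOD_Bayes", n_skipped)
}

#' Detection-limit report for a posterior
#'
#' LOD_1969, traditional LOQ and the Bayesian LOD for one electrode, in
#' molar and (when the analyte is known) ppm, with ppm limits also given at
#' the conventional one significant figure.
#'
#' @inheritParams lod_bayesian
#' @return Data frame with one row per limit.
#' @export
detection_limit_report <- function(draws, spec = lod_spec(),
                                   electrode_id = NULL, analyte = NULL) {
  if (is.null(analyte)) analyte <- draws$analyte
  iupac <- lod_iupac(draws, electrode_id, analyte)
  loq <- iupac
  loq$limit <- "LOQ"
  loq[, -1] <- lapply(iupac[, -1], loq_traditional)
  bayes <- lod_bayesian(draws, spec, electrode_id, analyte)
  out <- rbind(iupac, loq, bayes)
  if ("median_ppm" %in% names(out)) {
    out$display_ppm <- signif_limit(out$median_ppm)
  }
  rownames(out) <- NULL
  out
}
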