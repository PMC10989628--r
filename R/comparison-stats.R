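# Method-comparison analytics: Pearson correlation with its t-test p-value
# (plus OLS slope/intercept for completeness), extraction-recovery summaries,
# mean absolute log10 residuals against a reference method, and
# credible-interval width comparisons between estimation workflows.

#' Pearson correlation with p-value
#'
#' Sample Pearson r between two methods' concentrations and the two-sided
#' p-value from the t transform with n-2 degrees of freedom (via
#' [stats::cor.test()]); ordinary least-squares slope and intercept of B on
#' A are reported alongside. Computed on the raw concentration scale by
#' default, matching linear method-comparison plots; set `log = TRUE` for
#' the log10 scale.
#'
#' @param pairs Data frame with columns `value_A`, `value_B` (>= 3 complete
#'   pairs, both with non-zero variance); see [pair_comparison()].
#' @param log Correlate log10 values instead.
#' @return List with `r`, `p_value`, `n`, `slope`, `intercept`.
#' @export
pearson_with_p <- function(pairs, log = FALSE) {
  a <- pairs$value_A
  b <- pairs$value_B
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (log) {
    if (any(a <= 0) || any(b <= 0)) {
      stop("log correlation needs positive values", call. = FALSE)
    }
    a <- log10(a); b <- log10(b)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  ols <- stats::lm(b ~ a)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a),
       slope = unname(stats::coef(ols)[2]),
       intercept = unname(stats::coef(ols)[1]))
}

#' Extraction-recovery statistics
#'
#' Per-sample recovery of method B relative to method A,
#' `100 * value_B / value_A` (%), summarised as mean +/- sample sd. Samples
#' with a non-positive reference (A) value are excluded and counted.
#'
#' @param pairs Data frame with columns `value_A` (reference), `value_B`.
#' @return List with `mean`, `sd`, `n`, `n_excluded`.
#' @export
recovery_stats <- function(pairs) {
  a <- pairs$value_A
  b <- pairs$value_B
  keep <- is.finite(a) & is.finite(b) & a > 0
  n_excluded <- sum(!keep)
  rec <- 100 * b[keep] / a[keep]
  if (length(rec) == 0) stop("no usable pairs", call. = FALSE)
  list(mean = mean(rec), sd = if (length(rec) > 1) stats::sd(rec) else 0,
       n = length(rec), n_excluded = n_excluded)
}

#' Mean absolute log10 residual
#'
#' Mean over samples of `|log10(estimate) - log10(reference)|`, in decades,
#' using point estimates (posterior medians). Non-positive or censored
#' entries are excluded with a count.
#'
#' @param estimate Point estimates (linear scale, same unit as `reference`).
#' @param reference Reference values.
#' @param censored Optional logical vector flagging estimates to exclude.
#' @return List with `mal_residual` (decades), `n`, `n_excluded`.
#' @export
mean_abs_log_residual <- function(estimate, reference, censored = NULL) {
  if (is.null(censored)) censored <- rep(FALSE, length(estimate))
  keep <- is.finite(estimate) & is.finite(reference) &
    estimate > 0 & reference > 0 & !censored
  n_excluded <- sum(!keep)
  if (!any(keep)) stop("no usable pairs", call. = FALSE)
  list(mal_residual = mean(abs(log10(estimate[keep]) - log10(reference[keep]))),
       n = sum(keep), n_excluded = n_excluded)
}

#' Credible-interval width comparison between workflows
#'
#' Mean 95% credible-interval width (log10 decades) per estimate set, the
#' pairwise width ratio, and the percent reduction
#' `100 * (1 - width_B / width_A)` when moving from workflow A to B.
#'
#' @param width_A,width_B Vectors of 95% interval widths on the log10 scale
#'   (e.g. column `width95_log10` of an `ise_estimates` frame).
#' @return List with `mean_A`, `mean_B`, `ratio` (A/B) and `reduction_pct`.
#' @export
interval_width_stats <- function(width_A, width_B) {
  if (length(width_A) == 0 || length(width_B) == 0) {
    stop("empty estimate set", call. = FALSE)
  }
  ma <- mean(width_A)
  mb <- mean(width_B)
  list(mean_A = ma, mean_B = mb, ratio = ma / mb,
       reduction_pct = 100 * (1 - mb / ma))
}
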