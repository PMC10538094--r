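#' Construct a calibration batch
#'
#' Replicate instrument responses (analyte/IS peak-area ratios) at known
#' nominal concentrations, the input to [fit_calibration()].
#'
#' @param levels Nominal concentrations (ng/mL), one per response row;
#'   at least two distinct positive levels are required.
#' @param responses Instrument responses, same length as `levels`.
#' @param replicate Optional replicate index per row.
#' @return A data frame of class `calibration_batch` with columns `level`,
#'   `replicate`, `response`, ordered by level.
#' @export
calibration_batch <- function(levels, responses, replicate = NULL) {
  levels <- as.numeric(levels)
  responses <- as.numeric(responses)
  if (length(levels) != length(responses))
    stop("`levels` and `responses` must have equal length")
  if (any(!is.finite(levels)) || any(levels <= 0))
    stop("nominal levels must be positive and finite")
  if (any(!is.finite(responses))) stop("responses must be finite")
  if (length(unique(levels)) < 2L)
    stop("a calibration batch needs at least 2 distinct levels")
  if (is.null(replicate)) {
    replicate <- stats::ave(levels, levels, FUN = seq_along)
  }
  out <- data.frame(level = levels, replicate = as.integer(replicate),
                    response = responses)
  out <- out[order(out$level, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("calibration_batch", "data.frame")
  out
}

.weight_schemes <- c("unweighted", "1/x", "1/x^2")

.calibration_weights <- function(x, weighting) {
  weighting <- match.arg(weighting, .weight_schemes)
  switch(weighting,
         "unweighted" = rep(1, length(x)),
         "1/x" = 1 / x,
         "1/x^2" = 1 / x^2)
}

#' Fit a weighted linear calibration line
#'
#' Weighted least squares of response on nominal concentration,
#' minimising \eqn{\sum_i w_i (Y_i - a X_i - b)^2} with weights 1, 1/x or
#' 1/x^2. The coefficient of determination is computed on the weighted
#' regression (weighted residual and total sums of squares about the
#' weighted mean); the unweighted r^2 is reported alongside. Per-point
#' back-calculation residuals (percent deviation of the back-calculated
#' from the nominal concentration) are returned for standard-acceptance
#' checks.
#'
#' @param batch A [calibration_batch()].
#' @param weighting One of `"unweighted"`, `"1/x"`, `"1/x^2"`
#'   (x = nominal concentration). The assay convention is `"1/x"`, which is
#'   the default.
#' @return An object of class `calibration_fit`: a list with `slope`,
#'   `intercept`, `weighting`, `r_squared` (weighted), `r_squared_unweighted`,
#'   `n_points`, `residual_pct` (per-point back-calculation error, %), and
#'   the fitted `lm` object as `model`.
#' @examples
#' b <- simulate_calibration_batch(noise_cv = 0)  # exactly on the line
#' fit <- fit_calibration(b)
#' c(fit$slope, fit$intercept)
#' @export
fit_calibration <- function(batch, weighting = "1/x") {
  stopifnot(inherits(batch, "calibration_batch"))
  weighting <- match.arg(weighting, .weight_schemes)
  if (nrow(batch) < 2L) stop("need at least 2 calibration points")
  if (length(unique(batch$level)) < 2L)
    stop("all levels identical: singular design")
  w <- .calibration_weights(batch$level, weighting)
  model <- stats::lm(response ~ level, data = batch, weights = w)
  slope <- unname(stats::coef(model)[["level"]])
  intercept <- unname(stats::coef(model)[["(Intercept)"]])
  fitted <- slope * batch$level + intercept
  wmean <- sum(w * batch$response) / sum(w)
  ss_res <- sum(w * (batch$response - fitted)^2)
  ss_tot <- sum(w * (batch$response - wmean)^2)
  r2w <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  ss_res_u <- sum((batch$response - fitted)^2)
  ss_tot_u <- sum((batch$response - mean(batch$response))^2)
  r2u <- if (ss_tot_u > 0) 1 - ss_res_u / ss_tot_u else 1
  back <- (batch$response - intercept) / slope
  structure(list(slope = slope,
                 intercept = intercept,
                 weighting = weighting,
                 r_squared = max(0, min(1, r2w)),
                 r_squared_unweighted = max(0, min(1, r2u)),
                 n_points = nrow(batch),
                 residual_pct = 100 * (back - batch$level) / batch$level,
                 model = model),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (%s weighting, n = %d):\n", x$weighting, x$n_points))
  cat(sprintf("  Y = %.6g X + %.6g\n", x$slope, x$intercept))
  cat(sprintf("  r^2 (weighted)   = %.6f\n", x$r_squared))
  cat(sprintf("  r^2 (unweighted) = %.6f\n", x$r_squared_unweighted))
  invisible(x)
}

#' Back-calculate a concentration from an instrument response
#'
#' Inverts the calibration line: `(response - intercept) / slope`. Responses
#' below the intercept give negative concentrations; these are returned
#' unchanged but flagged `sub_blank` (an attribute), never clipped, so QC
#' statistics stay unbiased.
#'
#' @param fit A [fit_calibration()] result (or any list with `slope` and
#'   `intercept`).
#' @param response Instrument response(s).
#' @return Concentration(s) in ng/mL with logical attribute `"sub_blank"`.
#' @export
back_calculate <- function(fit, response) {
  if (!is.numeric(fit$slope) || fit$slope == 0)
    stop("calibration slope must be non-zero")
  conc <- (response - fit$intercept) / fit$slope
  attr(conc, "sub_blank") <- conc < 0
  conc
}

#' Evaluate a quality-control level: precision and accuracy
#'
#' Back-calculates replicate QC responses through the calibration fit and
#' summarises them as detected-concentration mean, precision (relative
#' standard deviation, RSD%) and accuracy
#' (100 * mean detected / nominal, %). Inter-day evaluations pool all
#' days' replicates into one call.
#'
#' @param fit A [fit_calibration()] result.
#' @param qc_responses Replicate instrument responses at one nominal level
#'   (at least two).
#' @param nominal Nominal concentration (ng/mL).
#' @param scope Label, e.g. `"intra-day"`, `"inter-day"`, `"day-1"`.
#' @return An object of class `qc_evaluation`: list with `nominal`,
#'   `detected_mean`, `rsd_pct`, `accuracy_pct`, `n`, `scope`.
#' @export
evaluate_qc <- function(fit, qc_responses, nominal, scope = "intra-day") {
  if (length(qc_responses) < 2L) stop("need at least 2 QC replicates")
  if (nominal <= 0) stop("`nominal` must be positive")
  detected <- back_calculate(fit, qc_responses)
  m <- mean(detected)
  if (m == 0) stop("mean detected concentration is zero: RSD undefined")
  structure(list(nominal = nominal,
                 detected_mean = m,
                 rsd_pct = 100 * stats::sd(detected) / m,
                 accuracy_pct = 100 * m / nominal,
                 n = length(detected),
                 scope = scope),
            class = "qc_evaluation")
}

#' @export
print.qc_evaluation <- function(x, ...) {
  cat(sprintf("QC %s: nominal %g ng/mL (n = %d)\n", x$scope, x$nominal, x$n))
  cat(sprintf("  Dect. Conc. = %.4g ng/mL, RSD = %.3g%%, Accu. = %.4g%%\n",
              x$detected_mean, x$rsd_pct, x$accuracy_pct))
  invisible(x)
}

#' @export
as.data.frame.qc_evaluation <- function(x, ...) {
  data.frame(scope = x$scope, nominal_ng_ml = x$nominal,
             detected_mean_ng_ml = x$detected_mean,
             rsd_pct = x$rsd_pct, accuracy_pct = x$accuracy_pct, n = x$n,
             stringsAsFactors = FALSE)
}

#' Check LOQ-level acceptance: accuracy 80-120%, precision within 20%
#'
#' Applies the lower-limit-of-quantification acceptance rule: accuracy
#' between 80 and 120% of nominal and RSD at most 20%, both bounds closed.
#' LOQ claims conventionally rest on seven replicate analyses; fewer
#' replicates trigger a warning but are still evaluated.
#'
#' @param eval A [evaluate_qc()] result.
#' @param min_n Replicate count below which a warning is issued (default 7).
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   violated bounds, empty on pass).
#' @export
check_loq_acceptance <- function(eval, min_n = 7L) {
  stopifnot(inherits(eval, "qc_evaluation"))
  if (eval$n < min_n)
    warning(sprintf("LOQ acceptance evaluated on n = %d replicates (< %d)", eval$n, min_n))
  reasons <- character(0)
  if (eval$accuracy_pct < 80 || eval$accuracy_pct > 120)
    reasons <- c(reasons, sprintf("accuracy %.4g%% outside 80-120%%", eval$accuracy_pct))
  if (eval$rsd_pct > 20)
    reasons <- c(reasons, sprintf("RSD %.4g%% exceeds 20%%", eval$rsd_pct))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Limits of detection and quantification from a signal-to-noise reference
#'
#' LOD and LOQ are the concentrations at signal-to-noise ratios of 3 and 10.
#' Assuming S/N proportional to concentration through the origin, a single
#' reference measurement (concentration, S/N) determines both:
#' `lod = 3 * conc / sn`, `loq = 10 * conc / sn`, so `loq/lod = 10/3`
#' always.
#'
#' @param reference_conc Reference concentration (ng/mL), `> 0`.
#' @param reference_sn Signal-to-noise ratio measured at that
#'   concentration, `> 0`.
#' @return Named numeric vector `c(lod = , loq = )` in ng/mL.
#' @examples
#' lod_loq_from_sn(7.5, 10)  # LOQ fixed point: 7.5 ng/mL
#' @export
lod_loq_from_sn <- function(reference_conc, reference_sn) {
  if (!is.numeric(reference_conc) || reference_conc <= 0)
    stop("`reference_conc` must be positive")
  if (!is.numeric(reference_sn) || reference_sn <= 0)
    stop("`reference_sn` must be positive")
  c(lod = 3 * reference_conc / reference_sn,
    loq = 10 * reference_conc / reference_sn)
}

#' Assess analyte stability against the +/-15% deviation rule
#'
#' Stability under a storage condition is expressed as the signed percent
#' deviation of the mean measured concentration from nominal; the sample is
#' stable when the absolute deviation is at most 15% (closed bound).
#'
#' @param measured Replicate detected concentrations (ng/mL), at least one.
#' @param nominal Nominal concentration (ng/mL), `> 0`.
#' @param condition Label, e.g. `"short-term"` (8 h at room temperature) or
#'   `"post-treatment"` (72 h at 4 C).
#' @return An object of class `stability_result`: list with `condition`,
#'   `nominal`, `deviation_pct`, `pass`, `n`.
#' @export
assess_stability <- function(measured, nominal, condition = "short-term") {
  if (length(measured) < 1L) stop("need at least 1 replicate")
  if (!is.numeric(nominal) || nominal <= 0) stop("`nominal` must be positive")
  dev <- 100 * (mean(measured) - nominal) / nominal
  structure(list(condition = condition, nominal = nominal,
                 deviation_pct = dev, pass = abs(dev) <= 15,
                 n = length(measured)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Stability (%s), nominal %g ng/mL, n = %d: deviation %+.2f%% -> %s\n",
              x$condition, x$nominal, x$n, x$deviation_pct,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
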