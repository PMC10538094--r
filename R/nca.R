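#' @title Noncompartmental analysis of single-dose concentration-time profiles
#' @description Per-subject NCA: observed Cmax/Tmax, lag time, best-fit
#'   terminal-phase log-linear regression (lambda-z), linear-trapezoidal AUC
#'   with Clast/lambda-z tail extrapolation, and the derived parameters
#'   t1/2 = ln2/lambda-z, CL/F = dose/AUC(0-inf) and Vd/F = CL/F/lambda-z.
#' @name nca
NULL

# quantifiable = reported (non-missing) and not flagged BLQ
.quantifiable <- function(profile) !profile$blq & !is.na(profile$conc)

#' Observed maximum concentration and its time
#'
#' Returns the largest quantifiable concentration and the sampling time at
#' which it occurs; ties are resolved to the earliest time.
#'
#' @param profile A [pk_profile()].
#' @return Named numeric vector `c(cmax = , tmax = )` (ng/mL, h).
#' @export
cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "pk_profile"))
  q <- .quantifiable(profile)
  if (!any(q)) stop("no quantifiable samples: Cmax undefined")
  conc <- profile$conc[q]
  times <- profile$times[q]
  i <- which.max(conc)  # which.max returns the first (earliest) maximum
  c(cmax = conc[i], tmax = times[i])
}

#' Estimate the absorption lag time from the observed profile
#'
#' The lag time is taken as the time of the last BLQ or zero sample
#' preceding the first quantifiable sample, and 0 when the first post-dose
#' sample is already quantifiable. On a sparse schedule the estimate is
#' grid-limited: it can only take observed sampling times.
#'
#' @param profile A [pk_profile()].
#' @return Lag time (h).
#' @export
estimate_tlag <- function(profile) {
  stopifnot(inherits(profile, "pk_profile"))
  q <- .quantifiable(profile)
  if (!any(q)) stop("no quantifiable samples: lag time undefined")
  first_q <- which(q)[1L]
  if (first_q == 1L) return(0)
  pre <- seq_len(first_q - 1L)
  lagged <- pre[profile$blq[pre] | (!is.na(profile$conc[pre]) & profile$conc[pre] == 0)]
  if (!length(lagged)) return(0)
  max(profile$times[lagged])
}

# Closed-form simple linear regression of y on x; returns slope and
# adjusted r^2. Used only inside the fast terminal-window scan; agreement
# with stats::lm is covered by tests.
.simple_reg <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  r2 <- if (syy > 0) (sxy * sxy) / (sxx * syy) else NaN
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(slope = slope, r2 = r2, r2_adj = r2_adj, n = n)
}

#' Select the terminal-phase window for the lambda-z regression
#'
#' Best-fit selection over candidate windows: every suffix (with at least
#' `min_points` points) of the quantifiable, positive-concentration samples
#' strictly after Tmax (the Cmax sample itself is excluded). The window
#' maximising the adjusted r^2 of the log-linear regression wins; windows
#' whose adjusted r^2 is within `tie_tol` of the maximum are tied and the
#' one with the most points is chosen, so an exactly mono-exponential tail
#' selects the full post-Tmax suffix.
#'
#' @param profile A [pk_profile()].
#' @param min_points Minimum points in a window (default 3).
#' @param tie_tol Adjusted-r^2 tolerance within which windows tie.
#' @return Integer vector of indices into the profile's samples, or
#'   `integer(0)` when fewer than `min_points` eligible points exist.
#' @export
select_terminal_phase <- function(profile, min_points = 3L, tie_tol = 1e-9) {
  stopifnot(inherits(profile, "pk_profile"))
  q <- .quantifiable(profile)
  if (!any(q)) return(integer(0))
  ct <- cmax_tmax(profile)
  eligible <- which(q & profile$times > ct[["tmax"]] & profile$conc > 0)
  if (length(eligible) < min_points) return(integer(0))
  starts <- seq_len(length(eligible) - min_points + 1L)
  best_r2 <- -Inf
  scores <- numeric(length(starts))
  npts <- integer(length(starts))
  for (s in starts) {
    idx <- eligible[s:length(eligible)]
    fit <- .simple_reg(profile$times[idx], log(profile$conc[idx]))
    scores[s] <- if (is.nan(fit$r2_adj)) -Inf else fit$r2_adj
    npts[s] <- length(idx)
  }
  if (all(!is.finite(scores))) return(integer(0))
  best <- max(scores)
  tied <- which(scores >= best - tie_tol)
  pick <- tied[which.max(npts[tied])]
  eligible[pick:length(eligible)]
}

#' Fit the terminal elimination rate constant (lambda-z)
#'
#' Ordinary least squares of the natural log concentration on time over the
#' given samples; lambda-z is the negated slope. A non-positive lambda-z
#' (non-decreasing tail) is returned with `valid = FALSE`.
#'
#' @param profile A [pk_profile()].
#' @param indices Indices of the samples to regress (from
#'   [select_terminal_phase()]); at least 3, all with positive
#'   concentrations.
#' @return List with `lambda_z` (1/h), `r2_adj`, `n_points`, `intercept`
#'   (log scale) and `valid`.
#' @export
fit_lambda_z <- function(profile, indices) {
  stopifnot(inherits(profile, "pk_profile"))
  if (length(indices) < 3L) stop("lambda-z regression needs at least 3 points")
  conc <- profile$conc[indices]
  times <- profile$times[indices]
  if (any(is.na(conc)) || any(conc <= 0))
    stop("lambda-z window must contain only positive quantifiable concentrations")
  model <- stats::lm(log(conc) ~ times)
  slope <- unname(stats::coef(model)[["times"]])
  lambda <- -slope
  # adjusted r^2 computed directly (summary.lm warns on perfect fits)
  y <- log(conc)
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  r2_plain <- if (ss_tot > 0) 1 - sum(stats::residuals(model)^2) / ss_tot else 1
  r2 <- 1 - (1 - r2_plain) * (n - 1) / (n - 2)
  list(lambda_z = lambda,
       r2_adj = r2,
       n_points = length(indices),
       intercept = unname(stats::coef(model)[["(Intercept)"]]),
       valid = is.finite(lambda) && lambda > 0)
}

#' Linear-trapezoidal area under the concentration-time curve
#'
#' Sums `(t[i+1]-t[i]) * (C[i]+C[i+1]) / 2` over the quantifiable-adjusted
#' series: BLQ samples at or before Tmax are treated as 0, BLQ samples after
#' Tmax are excluded.
#'
#' @param profile A [pk_profile()].
#' @param t_start,t_end Integration limits (h); default 0 to the last
#'   usable sample. Must bracket at least two usable samples.
#' @return AUC over the interval (h*ng/mL).
#' @export
auc_linear_trapezoid <- function(profile, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(profile, "pk_profile"))
  ser <- .auc_series(profile)
  if (is.null(t_start)) t_start <- min(ser$time)
  if (is.null(t_end)) t_end <- max(ser$time)
  if (t_start >= t_end) stop("`t_start` must be smaller than `t_end`")
  keep <- ser$time >= t_start & ser$time <= t_end
  if (sum(keep) < 2L) stop("fewer than 2 usable points in the integration interval")
  tt <- ser$time[keep]
  cc <- ser$conc[keep]
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

# BLQ handling for AUC: pre-/at-Tmax BLQ -> 0; post-Tmax BLQ dropped.
.auc_series <- function(profile) {
  q <- .quantifiable(profile)
  if (!any(q)) stop("no quantifiable samples: AUC undefined")
  tmax <- cmax_tmax(profile)[["tmax"]]
  conc <- profile$conc
  use <- rep(TRUE, length(conc))
  pre_blq <- profile$blq & profile$times <= tmax
  conc[pre_blq] <- 0
  use[profile$blq & profile$times > tmax] <- FALSE
  use[is.na(conc)] <- use[is.na(conc)] & FALSE
  list(time = profile$times[use], conc = conc[use])
}

#' Extrapolate the AUC to infinity
#'
#' Completes the observed AUC with the standard tail term
#' `Clast / lambda_z` and reports the extrapolated percentage; an
#' extrapolation above 20% of the total is flagged with a warning attribute
#' (common acceptance practice).
#'
#' @param auc_0_t Observed AUC to the last quantifiable sample (h*ng/mL).
#' @param c_last Last quantifiable concentration (ng/mL), `> 0`.
#' @param lambda_z Terminal rate constant (1/h), `> 0`.
#' @return List with `auc_0_inf`, `pct_extrapolated` and
#'   `extrapolation_warning`.
#' @export
auc_0_inf <- function(auc_0_t, c_last, lambda_z) {
  if (!is.numeric(lambda_z) || lambda_z <= 0)
    stop("cannot extrapolate: lambda_z must be positive")
  if (!is.numeric(c_last) || c_last <= 0)
    stop("`c_last` must be positive")
  tail_area <- c_last / lambda_z
  total <- auc_0_t + tail_area
  pct <- 100 * tail_area / total
  list(auc_0_inf = total, pct_extrapolated = pct,
       extrapolation_warning = pct > 20)
}

#' Derive half-life, clearance and volume from lambda-z and AUC
#'
#' `t1/2 = ln2 / lambda_z`; `CL/F = dose / AUC(0-inf)` with dose in mg
#' converted to ng (x 1e6) and the resulting mL/h converted to L/h
#' (/ 1e3), i.e. `CL/F (L/h) = 1000 * dose_mg / AUC (h*ng/mL)`;
#' `Vd/F = CL/F / lambda_z` (L).
#'
#' @param dose Administered dose (mg), `> 0`.
#' @param auc_0_inf AUC from 0 to infinity (h*ng/mL), `> 0`.
#' @param lambda_z Terminal rate constant (1/h), `> 0`.
#' @return Named numeric vector `c(t_half = , cl_over_f = , vd_over_f = )`
#'   in h, L/h and L.
#' @examples
#' derive_parameters(dose = 100, auc_0_inf = 1e5, lambda_z = log(2))
#' @export
derive_parameters <- function(dose, auc_0_inf, lambda_z) {
  if (dose <= 0 || auc_0_inf <= 0 || lambda_z <= 0)
    stop("`dose`, `auc_0_inf` and `lambda_z` must all be positive")
  cl <- dose * 1e6 / auc_0_inf / 1e3  # ng / (h*ng/mL) = mL/h, then -> L/h
  c(t_half = log(2) / lambda_z,
    cl_over_f = cl,
    vd_over_f = cl / lambda_z)
}

#' Run the full noncompartmental analysis for one subject
#'
#' Orchestrates [cmax_tmax()], [estimate_tlag()],
#' [select_terminal_phase()], [fit_lambda_z()], [auc_linear_trapezoid()],
#' [auc_0_inf()] and [derive_parameters()]. Any stage failure yields a
#' structured per-subject error record (class `nca_error`) instead of an
#' exception, so population runs never crash on one bad subject.
#'
#' @param profile A [pk_profile()].
#' @param dose Dose (mg); defaults to the profile's dose.
#' @param min_quantifiable Minimum quantifiable samples required (default 3).
#' @return An object of class `nca_result` (named list of parameters and a
#'   `flags` character vector), or of class `nca_error` with `subject_id`
#'   and `message`.
#' @examples
#' prof <- simulate_profile(pk_params(), c(0, 0.5, 1, 1.5, 2, 3, 5, 8, 24))
#' run_nca(prof)
#' @export
run_nca <- function(profile, dose = profile$dose, min_quantifiable = 3L) {
  stopifnot(inherits(profile, "pk_profile"))
  err <- function(msg) structure(list(subject_id = profile$subject_id,
                                      message = msg),
                                 class = "nca_error")
  q <- .quantifiable(profile)
  if (sum(q) < min_quantifiable)
    return(err("insufficient quantifiable data"))
  out <- tryCatch({
    ct <- cmax_tmax(profile)
    tlag <- estimate_tlag(profile)
    flags <- character(0)
    idx <- select_terminal_phase(profile)
    lz <- NA_real_; lz_n <- NA_integer_; lz_r2 <- NA_real_
    if (!length(idx)) {
      flags <- c(flags, "lambda_z_unavailable")
    } else {
      fit <- fit_lambda_z(profile, idx)
      if (!fit$valid) {
        flags <- c(flags, "lambda_z_not_positive")
      } else {
        lz <- fit$lambda_z
        lz_n <- fit$n_points
        lz_r2 <- fit$r2_adj
      }
    }
    auc_t <- auc_linear_trapezoid(profile)
    ser <- .auc_series(profile)
    pos <- ser$conc > 0
    c_last <- ser$conc[pos][sum(pos)]
    if (is.na(lz)) {
      res_inf <- list(auc_0_inf = NA_real_, pct_extrapolated = NA_real_,
                      extrapolation_warning = FALSE)
      derived <- c(t_half = NA_real_, cl_over_f = NA_real_, vd_over_f = NA_real_)
    } else {
      res_inf <- auc_0_inf(auc_t, c_last, lz)
      if (res_inf$extrapolation_warning)
        flags <- c(flags, "extrapolation_gt_20pct")
      derived <- derive_parameters(dose, res_inf$auc_0_inf, lz)
    }
    structure(list(subject_id = profile$subject_id,
                   dose = dose,
                   cmax = ct[["cmax"]],
                   tmax = ct[["tmax"]],
                   tlag = tlag,
                   lambda_z = lz,
                   lambda_z_n_points = lz_n,
                   lambda_z_r2_adj = lz_r2,
                   t_half = derived[["t_half"]],
                   auc_0_t = auc_t,
                   auc_0_inf = res_inf$auc_0_inf,
                   pct_extrapolated = res_inf$pct_extrapolated,
                   cl_over_f = derived[["cl_over_f"]],
                   vd_over_f = derived[["vd_over_f"]],
                   flags = flags),
              class = "nca_result")
  }, error = function(e) err(conditionMessage(e)))
  out
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA result for subject %s (dose %g mg):\n", x$subject_id, x$dose))
  cat(sprintf("  Cmax  = %.4g ng/mL at Tmax = %g h (tlag %g h)\n",
              x$cmax, x$tmax, x$tlag))
  cat(sprintf("  lambda_z = %.4g 1/h (n = %s, adj r^2 = %.4g); t1/2 = %.4g h\n",
              x$lambda_z, format(x$lambda_z_n_points), x$lambda_z_r2_adj, x$t_half))
  cat(sprintf("  AUC0-t = %.5g, AUC0-inf = %.5g h*ng/mL (%.2g%% extrapolated)\n",
              x$auc_0_t, x$auc_0_inf, x$pct_extrapolated))
  cat(sprintf("  CL/F = %.4g L/h; Vd/F = %.4g L\n", x$cl_over_f, x$vd_over_f))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.nca_error <- function(x, ...) {
  cat(sprintf("NCA failed for subject %s: %s\n", x$subject_id, x$message))
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(subject_id = x$subject_id, dose_mg = x$dose, cmax = x$cmax,
             tmax = x$tmax, tlag = x$tlag, lambda_z = x$lambda_z,
             lambda_z_n_points = x$lambda_z_n_points,
             lambda_z_r2_adj = x$lambda_z_r2_adj, t_half = x$t_half,
             auc_0_t = x$auc_0_t, auc_0_inf = x$auc_0_inf,
             pct_extrapolated = x$pct_extrapolated,
             cl_over_f = x$cl_over_f, vd_over_f = x$vd_over_f,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

.summary_parameters <- c("cmax", "tmax", "tlag", "lambda_z", "t_half",
                         "auc_0_t", "auc_0_inf", "cl_over_f", "vd_over_f")

#' Summarise NCA results across subjects
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of each
#' parameter over successfully analysed subjects; per-subject parameters are
#' averaged, never recomputed as ratios of averages. Failed subjects
#' (`nca_error` records, or results with an unavailable parameter) are
#' excluded from that parameter's n and counted.
#'
#' @param results List of [run_nca()] outputs (`nca_result` and/or
#'   `nca_error` records).
#' @return A data frame of class `population_summary` with columns
#'   `parameter`, `mean`, `sd`, `n`, plus attributes `n_total`, `n_failed`
#'   and `failed_subjects`.
#' @export
summarize_population <- function(results) {
  if (!length(results)) stop("no NCA results to summarise")
  ok <- vapply(results, inherits, logical(1), what = "nca_result")
  if (!any(ok)) stop("no successful NCA results to summarise")
  failed <- results[!ok]
  good <- results[ok]
  rows <- lapply(.summary_parameters, function(p) {
    vals <- vapply(good, function(r) as.numeric(r[[p]]), numeric(1))
    vals <- vals[is.finite(vals)]
    data.frame(parameter = p,
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) >= 2) stats::sd(vals) else NA_real_,
               n = length(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_total") <- length(results)
  attr(out, "n_failed") <- sum(!ok)
  attr(out, "failed_subjects") <- unname(vapply(failed, function(e) e$subject_id, character(1)))
  class(out) <- c("population_summary", "data.frame")
  out
}

.summary_labels <- c(cmax = "Cmax (ng/mL)", tmax = "Tmax (h)",
                     tlag = "tlag (h)", lambda_z = "lambda_z (1/h)",
                     t_half = "t1/2 (h)", auc_0_t = "AUC0-t (h*ng/mL)",
                     auc_0_inf = "AUC0-inf (h*ng/mL)",
                     cl_over_f = "CL/F (L/h)", vd_over_f = "Vd/F (L)")

#' @export
print.population_summary <- function(x, digits = 4, ...) {
  n_total <- attr(x, "n_total")
  n_failed <- attr(x, "n_failed")
  cat(sprintf("Population PK summary (mean +/- SD; %d subjects analysed, %d excluded):\n",
              n_total - n_failed, n_failed))
  for (i in seq_len(nrow(x))) {
    lab <- .summary_labels[[x$parameter[i]]]
    cat(sprintf("  %-22s %s +/- %s (n = %d)\n", lab,
                format(signif(x$mean[i], digits)),
                format(signif(x$sd[i], digits)), x$n[i]))
  }
  invisible(x)
}
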