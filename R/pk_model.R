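#' Pharmacokinetic parameter set for the one-compartment oral model
#'
#' Bundles the structural parameters of a one-compartment model with
#' first-order absorption, first-order elimination and an absorption lag.
#' These are the generative quantities behind the synthetic serum profiles;
#' `kel`, `vd_over_f` and `dose` correspond to the quantities a
#' noncompartmental analysis estimates, while `ka` and `tlag` are
#' simulator-side parameters.
#'
#' Defaults describe a 100 mg oral dose with a terminal half-life of about
#' 3.9 h (`kel = log(2)/3.93`), an apparent volume of 1500 L, and an
#' absorption rate placing the noise-free peak near 1.1 h post dose.
#'
#' @param ka First-order absorption rate constant (1/h). Must differ from
#'   `kel` (the degenerate `ka == kel` form is not supported).
#' @param kel First-order elimination rate constant (1/h).
#' @param vd_over_f Apparent volume of distribution, Vd/F (L).
#' @param tlag Absorption lag time (h), `>= 0`.
#' @param dose Administered oral dose (mg).
#' @return An object of class `pk_params` (a named list).
#' @examples
#' p <- pk_params()
#' conc_one_cpt(p, times = c(0, 0.5, 1, 2, 8))
#' @export
pk_params <- function(ka = 3.0,
                      kel = log(2) / 3.93,
                      vd_over_f = 1500,
                      tlag = 0.1,
                      dose = 100) {
  stopifnot(is.numeric(ka), length(ka) == 1L, is.finite(ka),
            is.numeric(kel), length(kel) == 1L, is.finite(kel),
            is.numeric(vd_over_f), length(vd_over_f) == 1L,
            is.numeric(tlag), length(tlag) == 1L,
            is.numeric(dose), length(dose) == 1L)
  if (ka <= 0) stop("`ka` must be positive")
  if (kel <= 0) stop("`kel` must be positive")
  if (ka == kel) stop("`ka` must differ from `kel`: the flip-flop degenerate form is not supported")
  if (vd_over_f <= 0) stop("`vd_over_f` must be positive")
  if (tlag < 0) stop("`tlag` must be non-negative")
  if (dose <= 0) stop("`dose` must be positive")
  structure(list(ka = ka, kel = kel, vd_over_f = vd_over_f,
                 tlag = tlag, dose = dose),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("One-compartment oral PK parameters:\n")
  cat(sprintf("  ka        = %.4g 1/h\n", x$ka))
  cat(sprintf("  kel       = %.4g 1/h (t1/2 = %.3g h)\n", x$kel, log(2) / x$kel))
  cat(sprintf("  Vd/F      = %.4g L\n", x$vd_over_f))
  cat(sprintf("  tlag      = %.4g h\n", x$tlag))
  cat(sprintf("  dose      = %.4g mg\n", x$dose))
  invisible(x)
}

# dose mg -> ng and volume L -> mL, so concentrations come out in ng/mL.
# This is the single place the unit conversion is applied for the model.
.dose_ng <- function(dose_mg) dose_mg * 1e6
.vd_ml <- function(vd_l) vd_l * 1e3

#' Noise-free serum concentration under the one-compartment oral model
#'
#' Evaluates
#' \deqn{C(t) = \frac{D \, k_a}{V (k_a - k_{el})}
#'   \left( e^{-k_{el}(t - t_{lag})} - e^{-k_a (t - t_{lag})} \right)}
#' for `t > tlag` and 0 otherwise, with the dose in ng and the volume in mL
#' so that `C` is in ng/mL.
#'
#' @param params A [pk_params()] object.
#' @param times Sampling times (h), non-negative.
#' @return Numeric vector of concentrations (ng/mL), same length as `times`.
#' @export
conc_one_cpt <- function(params, times) {
  stopifnot(inherits(params, "pk_params"))
  if (length(times) == 0L) stop("`times` must be non-empty")
  if (any(!is.finite(times)) || any(times < 0)) stop("`times` must be finite and non-negative")
  d <- .dose_ng(params$dose)
  v <- .vd_ml(params$vd_over_f)
  tt <- pmax(times - params$tlag, 0)
  a <- d * params$ka / (v * (params$ka - params$kel))
  conc <- a * (exp(-params$kel * tt) - exp(-params$ka * tt))
  conc[times <= params$tlag] <- 0
  conc
}

#' Analytic peak time of the noise-free model
#'
#' `t* = ln(ka/kel) / (ka - kel) + tlag`, the continuous-time maximum of
#' [conc_one_cpt()].
#'
#' @inheritParams conc_one_cpt
#' @return Time of maximum concentration (h).
#' @export
tmax_analytic <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  log(params$ka / params$kel) / (params$ka - params$kel) + params$tlag
}

#' Analytic area under the noise-free model from 0 to infinity
#'
#' Equals `dose / (vd_over_f * kel)` after the mg/L to ng/mL unit
#' conversion, independent of `ka` and `tlag`.
#'
#' @inheritParams conc_one_cpt
#' @return AUC from 0 to infinity (h*ng/mL).
#' @export
auc_analytic <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  .dose_ng(params$dose) / (.vd_ml(params$vd_over_f) * params$kel)
}

#' Construct a concentration-time profile
#'
#' The container for one subject's dosed serum time course, the input to the
#' noncompartmental analysis. Concentrations are `NA` where the sample is
#' censored below the limit of quantification (the `blq` flag is then
#' `TRUE`).
#'
#' @param subject_id Subject label.
#' @param dose Administered dose (mg).
#' @param times Strictly increasing sampling times (h).
#' @param conc Concentrations (ng/mL); `NA` where censored.
#' @param blq Logical BLQ flags, same length as `times`.
#' @return An object of class `pk_profile`.
#' @export
pk_profile <- function(subject_id, dose, times, conc,
                       blq = rep(FALSE, length(times))) {
  times <- as.numeric(times)
  conc <- as.numeric(conc)
  blq <- as.logical(blq)
  if (length(times) != length(conc) || length(times) != length(blq))
    stop("`times`, `conc` and `blq` must have equal length")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(times < 0)) stop("`times` must be non-negative")
  if (any(conc[!is.na(conc)] < 0)) stop("concentrations must be non-negative")
  if (any(is.na(conc) & !blq)) stop("missing concentrations must carry a BLQ flag")
  structure(list(subject_id = as.character(subject_id),
                 dose = as.numeric(dose),
                 times = times, conc = conc, blq = blq),
            class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("Concentration-time profile: subject %s, dose %g mg, %d samples (%d BLQ)\n",
              x$subject_id, x$dose, length(x$times), sum(x$blq)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.pk_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id,
             dose_mg = x$dose,
             time_h = x$times,
             conc_ng_ml = x$conc,
             blq = x$blq,
             stringsAsFactors = FALSE)
}

#' Simulate one noise-free, uncensored concentration-time profile
#'
#' Evaluates the one-compartment oral model on a sampling schedule. The
#' result carries no assay noise and no BLQ censoring; see
#' [simulate_population()] for the stochastic generator.
#'
#' @param params A [pk_params()] object.
#' @param schedule Strictly increasing sampling times (h).
#' @param subject_id Label for the resulting profile.
#' @return A [pk_profile()].
#' @examples
#' prof <- simulate_profile(pk_params(), schedule = c(0, 0.5, 1, 1.5, 2, 3, 5, 8, 24))
#' prof$conc
#' @export
simulate_profile <- function(params, schedule, subject_id = "S1") {
  stopifnot(inherits(params, "pk_params"))
  if (length(schedule) == 0L) stop("`schedule` must be non-empty")
  conc <- conc_one_cpt(params, schedule)
  pk_profile(subject_id, params$dose, schedule, conc)
}
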