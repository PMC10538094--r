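#' Population simulation configuration
#'
#' Describes the generative model for a simulated single-dose serum study:
#' typical one-compartment parameters, log-normal inter-individual
#' variability (IIV), proportional assay noise, the sampling schedule and
#' censoring below the lower limit of quantification (LLOQ).
#'
#' Defaults reproduce the study design the package emulates: a 100 mg oral
#' dose, sampling before dosing (0) and at 0.5, 1.0, 1.5, 2.0, 3.0, 5.0,
#' 8.0 and 24 h, ten subjects, and an LLOQ of 7.5 ng/mL.
#'
#' @param typical A [pk_params()] object of typical-value parameters.
#' @param iiv_cv Named numeric vector of IIV coefficients of variation
#'   (fractions) for any of `ka`, `kel`, `vd_over_f`. Parameters are drawn
#'   log-normally with mean equal to the typical value. `tlag` is varied
#'   uniformly on `typical$tlag` +/- `tlag_halfwidth`, clipped at 0.
#' @param assay_cv Proportional measurement-error CV (fraction).
#' @param lloq Lower limit of quantification (ng/mL); simulated samples
#'   below it are censored. Use 0 to disable censoring.
#' @param schedule Ordered sampling times (h); must start at 0 (predose).
#' @param n_subjects Number of subjects.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param tlag_halfwidth Half-width (h) of the uniform lag-time interval.
#' @return An object of class `population_config`.
#' @export
population_config <- function(typical = pk_params(),
                              iiv_cv = c(ka = 0.4, kel = 0.4, vd_over_f = 0.4),
                              assay_cv = 0.05,
                              lloq = 7.5,
                              schedule = c(0, 0.5, 1, 1.5, 2, 3, 5, 8, 24),
                              n_subjects = 10,
                              seed = 20230101,
                              tlag_halfwidth = 0.1) {
  stopifnot(inherits(typical, "pk_params"))
  iiv <- c(ka = 0, kel = 0, vd_over_f = 0)
  if (length(iiv_cv)) {
    if (is.null(names(iiv_cv)) && length(iiv_cv) == 1L) {
      iiv[] <- iiv_cv
    } else {
      bad <- setdiff(names(iiv_cv), names(iiv))
      if (length(bad)) stop("unknown iiv_cv names: ", paste(bad, collapse = ", "))
      iiv[names(iiv_cv)] <- iiv_cv
    }
  }
  if (any(iiv < 0)) stop("IIV CVs must be non-negative")
  if (assay_cv < 0) stop("`assay_cv` must be non-negative")
  if (lloq < 0) stop("`lloq` must be non-negative")
  if (length(schedule) < 1L || any(diff(schedule) <= 0))
    stop("`schedule` must be strictly increasing")
  if (schedule[1L] != 0) stop("`schedule` must start with the predose time 0")
  if (n_subjects < 1L) stop("`n_subjects` must be at least 1")
  if (tlag_halfwidth < 0) stop("`tlag_halfwidth` must be non-negative")
  structure(list(typical = typical, iiv_cv = iiv, assay_cv = assay_cv,
                 lloq = lloq, schedule = as.numeric(schedule),
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed),
                 tlag_halfwidth = tlag_halfwidth),
            class = "population_config")
}

# Log-normal draw with E[X] = typical and CV = cv (mean parameterisation:
# meanlog = log(typical) - sdlog^2/2, sdlog^2 = log(1 + cv^2)).
.rlnorm_cv <- function(n, typical, cv) {
  if (cv == 0) return(rep(typical, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(typical) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a population of concentration-time profiles
#'
#' Draws per-subject parameters log-normally around the typical values (mean
#' parameterisation, so the population mean of each parameter equals its
#' typical value), evaluates the one-compartment oral model on the sampling
#' schedule, applies proportional assay noise, and censors samples below the
#' LLOQ. The predose sample is recorded as exactly 0 and flagged BLQ.
#'
#' @param config A [population_config()].
#' @return A list of [pk_profile()] objects with attribute `"parameters"`:
#'   a data frame of the per-subject generative parameters (for
#'   parameter-recovery testing).
#' @examples
#' profs <- simulate_population(population_config(n_subjects = 3, seed = 42))
#' length(profs)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  ty <- config$typical
  n <- config$n_subjects
  ka <- .rlnorm_cv(n, ty$ka, config$iiv_cv[["ka"]])
  kel <- .rlnorm_cv(n, ty$kel, config$iiv_cv[["kel"]])
  vd <- .rlnorm_cv(n, ty$vd_over_f, config$iiv_cv[["vd_over_f"]])
  if (config$tlag_halfwidth > 0) {
    tlag <- stats::runif(n, max(0, ty$tlag - config$tlag_halfwidth),
                         ty$tlag + config$tlag_halfwidth)
  } else {
    tlag <- rep(ty$tlag, n)
  }
  pars <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                     ka = ka, kel = kel, vd_over_f = vd, tlag = tlag,
                     dose = ty$dose, stringsAsFactors = FALSE)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pk_params(ka = ka[i], kel = kel[i], vd_over_f = vd[i],
                   tlag = tlag[i], dose = ty$dose)
    conc <- conc_one_cpt(p, config$schedule)
    if (config$assay_cv > 0) {
      conc <- pmax(0, conc * (1 + stats::rnorm(length(conc), 0, config$assay_cv)))
    }
    prof <- pk_profile(pars$subject_id[i], ty$dose, config$schedule, conc)
    profiles[[i]] <- if (config$lloq > 0) censor_blq(prof, config$lloq) else prof
  }
  names(profiles) <- pars$subject_id
  attr(profiles, "parameters") <- pars
  profiles
}

#' Censor a profile below the limit of quantification
#'
#' Samples with concentration strictly below `lloq` are flagged BLQ and
#' their value masked (`NA`); all other samples are unchanged. Already
#' censored samples stay censored, so the operation is idempotent.
#'
#' @param profile A [pk_profile()].
#' @param lloq Lower limit of quantification (ng/mL), `> 0`.
#' @return The censored [pk_profile()], with attribute `"n_blq"` giving the
#'   total number of BLQ flags.
#' @examples
#' p <- pk_profile("S1", 100, c(0.5, 1, 2), c(5, 7.5, 80))
#' censor_blq(p, 7.5)$blq
#' @export
censor_blq <- function(profile, lloq) {
  stopifnot(inherits(profile, "pk_profile"))
  if (!is.numeric(lloq) || length(lloq) != 1L || lloq <= 0)
    stop("`lloq` must be a single positive number")
  below <- !is.na(profile$conc) & profile$conc < lloq
  profile$blq <- profile$blq | below
  profile$conc[profile$blq] <- NA_real_
  attr(profile, "n_blq") <- sum(profile$blq)
  profile
}

#' Simulate a calibration batch with concentration-proportional noise
#'
#' Generates replicate instrument responses (analyte/internal-standard peak
#' area ratios) at the given nominal levels from a straight line with
#' zero-mean Gaussian noise whose standard deviation is proportional to
#' concentration (`sd = noise_cv * slope * level`). This is the variance
#' structure that motivates 1/x weighting in the calibration fit.
#'
#' @param slope,intercept True line coefficients (response per ng/mL;
#'   response units).
#' @param levels Nominal concentrations (ng/mL), defaulting to the seven
#'   standard levels 7.5-500 ng/mL.
#' @param replicates Replicates per level.
#' @param noise_cv Proportional noise CV (fraction); 0 gives responses
#'   exactly on the line.
#' @param seed Integer RNG seed.
#' @return A [calibration_batch()] with columns `level`, `replicate`,
#'   `response`.
#' @examples
#' b <- simulate_calibration_batch(noise_cv = 0.03, seed = 1)
#' nrow(b)  # 7 levels x 2 replicates
#' @export
simulate_calibration_batch <- function(slope = 0.8466, intercept = 12.36,
                                       levels = c(7.5, 10, 25, 50, 100, 250, 500),
                                       replicates = 2, noise_cv = 0,
                                       seed = NULL) {
  if (any(levels <= 0)) stop("`levels` must be positive")
  if (replicates < 1L) stop("`replicates` must be at least 1")
  if (noise_cv < 0) stop("`noise_cv` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  lev <- rep(levels, each = replicates)
  rep_id <- rep(seq_len(replicates), times = length(levels))
  resp <- slope * lev + intercept
  if (noise_cv > 0) {
    resp <- resp + stats::rnorm(length(lev), 0, noise_cv * slope * lev)
  }
  calibration_batch(lev, resp, replicate = rep_id)
}

#' Simulate a low-exposure comparison arm
#'
#' Models a second study arm in which the administered compound converts to
#' the measured analyte with low efficiency: the same one-compartment model
#' driven by `dose * conversion_fraction`, while profiles record the
#' administered dose. With the default 0.1 conversion on a 90 mg dose,
#' concentrations sit around one-tenth of the main arm and most samples fall
#' below a 7.5 ng/mL LLOQ - the guard-rail scenario for BLQ-heavy data.
#' This is a labelled heuristic for generating censoring-dominated arms,
#' not a mechanistic conversion model.
#'
#' @param config A [population_config()]; its typical dose is replaced.
#' @param dose Administered dose of the precursor compound (mg).
#' @param conversion_fraction Fraction of the dose reaching circulation as
#'   the measured analyte, in (0, 1].
#' @return A list of [pk_profile()] objects, as [simulate_population()].
#' @export
simulate_low_exposure_arm <- function(config, dose = 90,
                                      conversion_fraction = 0.1) {
  stopifnot(inherits(config, "population_config"))
  if (conversion_fraction <= 0 || conversion_fraction > 1)
    stop("`conversion_fraction` must be in (0, 1]")
  ty <- config$typical
  config$typical <- pk_params(ka = ty$ka, kel = ty$kel,
                              vd_over_f = ty$vd_over_f, tlag = ty$tlag,
                              dose = dose * conversion_fraction)
  profiles <- simulate_population(config)
  lapply(profiles, function(pr) { pr$dose <- dose; pr })
}
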