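#' Default run configuration
#'
#' All tunables with their assay defaults: the seven calibration levels
#' 7.5-500 ng/mL on the printed line slope/intercept, LLOQ 7.5 ng/mL, the
#' 0, 0.5, 1, 1.5, 2, 3, 5, 8, 24 h schedule, a 100 mg dose, ten subjects,
#' 1/x weighting, and the 80-120% / 20% / +-15% acceptance bounds.
#'
#' @param mode One of `"simulate"`, `"calibrate"`, `"validate"`, `"nca"`,
#'   `"full"`.
#' @param seed Integer seed recorded in all outputs.
#' @return A named list accepted by [run_pipeline()].
#' @export
default_run_config <- function(mode = "full", seed = 20230101) {
  list(mode = mode,
       seed = as.integer(seed),
       input = NULL,
       output_dir = "ncakit-run",
       population = list(ka = 3.0, kel = log(2) / 3.93, vd_over_f = 1500,
                         tlag = 0.1, dose = 100,
                         iiv_cv = c(ka = 0.4, kel = 0.4, vd_over_f = 0.4),
                         assay_cv = 0.05, lloq = 7.5,
                         schedule = c(0, 0.5, 1, 1.5, 2, 3, 5, 8, 24),
                         n_subjects = 10),
       calibration = list(levels = c(7.5, 10, 25, 50, 100, 250, 500),
                          replicates = 2, slope = 0.8466, intercept = 12.36,
                          noise_cv = 0.03, weighting = "1/x",
                          qc_levels = c(50, 250), qc_replicates = 4,
                          qc_days = 3, qc_noise_cv = 0.01,
                          loq_replicates = 7, loq_noise_cv = 0.05,
                          accuracy_bounds = c(80, 120), rsd_max = 20,
                          stability_tol = 15),
       nca = list(min_quantifiable = 3, lambda_z_min_points = 3,
                  extrapolation_warn_pct = 20))
}

.population_config_from <- function(cfg) {
  p <- cfg$population
  population_config(
    typical = pk_params(ka = p$ka, kel = p$kel, vd_over_f = p$vd_over_f,
                        tlag = p$tlag, dose = p$dose),
    iiv_cv = unlist(p$iiv_cv), assay_cv = p$assay_cv, lloq = p$lloq,
    schedule = as.numeric(p$schedule), n_subjects = p$n_subjects,
    seed = cfg$seed)
}

# fill omitted fields of a user config with package defaults, recursively
.merge_config <- function(user, defaults) {
  for (k in names(defaults)) {
    if (is.null(user[[k]])) {
      user[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      user[[k]] <- .merge_config(user[[k]], defaults[[k]])
    }
  }
  user
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stamp <- function(cfg, out_dir, artifacts) {
  meta <- list(seed = cfg$seed, mode = cfg$mode,
               config_md5 = .config_hash(cfg),
               artifacts = as.list(stats::setNames(basename(artifacts),
                                                   names(artifacts))))
  path <- file.path(out_dir, "run_meta.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  c(artifacts, run_meta = path)
}

#' Run a reproducible analysis pipeline
#'
#' Binds the three analysis stages into seeded, file-based runs:
#' \describe{
#'   \item{simulate}{generate a study population and a calibration batch,
#'     write them as CSV.}
#'   \item{calibrate}{fit the weighted calibration line to a batch (from
#'     `config$input` or freshly simulated) and write the fit summary.}
#'   \item{validate}{run the method-validation battery (calibration
#'     linearity, intra/inter-day QC, LOQ acceptance, stability) on
#'     synthetic batches and write a report in the standard
#'     detected-concentration / RSD% / accuracy% layout.}
#'   \item{nca}{noncompartmental analysis of profiles from `config$input`,
#'     with per-subject results, a population summary and a JSON log of
#'     terminal-window choices and flags.}
#'   \item{full}{simulate, quantify the simulated samples through the
#'     calibration layer (response = line(concentration), then
#'     back-calculation), run the NCA, and write all reports.}
#' }
#' Every artifact directory is stamped with the config hash and seed
#' (`run_meta.json`); identical configs and seeds give identical artifacts.
#'
#' @param config Named list as from [default_run_config()] or
#'   [read_run_config()], or a path to a YAML/JSON config. Omitted fields
#'   take the defaults.
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a list with `status` (0 on success) and `artifacts`
#'   (named paths).
#' @export
run_pipeline <- function(config = default_run_config(), output_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  config <- .merge_config(config, default_run_config())
  mode <- match.arg(config$mode, c("simulate", "calibrate", "validate", "nca", "full"))
  config$mode <- mode
  out_dir <- if (!is.null(output_dir)) output_dir else config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  cal <- config$calibration

  if (mode %in% c("simulate", "full")) {
    profiles <- simulate_population(.population_config_from(config))
    ppath <- file.path(out_dir, "profiles.csv")
    write_profiles(profiles, ppath)
    batch <- simulate_calibration_batch(cal$slope, cal$intercept,
                                        as.numeric(cal$levels), cal$replicates,
                                        cal$noise_cv, seed = config$seed + 1L)
    bpath <- file.path(out_dir, "calibration_batch.csv")
    write_calibration_batch(batch, bpath)
    artifacts <- c(artifacts, profiles = ppath, calibration_batch = bpath)
  }

  if (mode %in% c("calibrate", "validate", "full")) {
    if (mode == "calibrate" && !is.null(config$input)) {
      batch <- read_calibration_batch(config$input)
    } else if (mode != "full") {
      batch <- simulate_calibration_batch(cal$slope, cal$intercept,
                                          as.numeric(cal$levels), cal$replicates,
                                          cal$noise_cv, seed = config$seed + 1L)
    }
    fit <- fit_calibration(batch, cal$weighting)
    fpath <- file.path(out_dir, "calibration_fit.csv")
    utils::write.csv(data.frame(slope = fit$slope, intercept = fit$intercept,
                                weighting = fit$weighting,
                                r_squared = fit$r_squared,
                                r_squared_unweighted = fit$r_squared_unweighted,
                                n_points = fit$n_points),
                     fpath, row.names = FALSE)
    artifacts <- c(artifacts, calibration_fit = fpath)
  }

  if (mode == "validate") {
    report <- validate_method(fit, cal, seed = config$seed + 2L)
    vpath <- file.path(out_dir, "validation_report.csv")
    utils::write.csv(report$table, vpath, row.names = FALSE)
    tpath <- file.path(out_dir, "validation_report.txt")
    writeLines(report$text, tpath)
    artifacts <- c(artifacts, validation_csv = vpath, validation_txt = tpath)
    if (!report$all_pass) {
      message("validation: one or more acceptance checks failed")
    }
  }

  if (mode %in% c("nca", "full")) {
    if (mode == "nca") {
      if (is.null(config$input)) stop("nca mode requires `input` profiles CSV")
      profiles <- read_profiles(config$input, lloq = config$population$lloq)
    } else {
      # quantification step: simulated concentrations -> instrument response
      # via the true line, then back through the fitted calibration
      profiles <- lapply(profiles, function(pr) {
        q <- !pr$blq & !is.na(pr$conc)
        resp <- cal$slope * pr$conc[q] + cal$intercept
        pr$conc[q] <- pmax(0, back_calculate(fit, resp))
        censor_blq(pr, config$population$lloq)
      })
    }
    results <- lapply(profiles, run_nca,
                      min_quantifiable = config$nca$min_quantifiable)
    ok <- vapply(results, inherits, logical(1), "nca_result")
    rpath <- file.path(out_dir, "nca_results.csv")
    if (any(ok)) {
      utils::write.csv(do.call(rbind, lapply(results[ok], as.data.frame)),
                       rpath, row.names = FALSE)
    } else {
      utils::write.csv(data.frame(), rpath, row.names = FALSE)
    }
    summ <- if (any(ok)) summarize_population(results) else NULL
    spath <- file.path(out_dir, "population_summary.csv")
    if (!is.null(summ)) utils::write.csv(as.data.frame(summ), spath, row.names = FALSE)
    log <- lapply(results, function(r) {
      if (inherits(r, "nca_error")) {
        list(subject_id = r$subject_id, status = "error", message = r$message)
      } else {
        list(subject_id = r$subject_id, status = "ok",
             lambda_z = r$lambda_z, lambda_z_n_points = r$lambda_z_n_points,
             flags = r$flags)
      }
    })
    lpath <- file.path(out_dir, "nca_log.json")
    jsonlite::write_json(list(seed = config$seed, subjects = log), lpath,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    artifacts <- c(artifacts, nca_results = rpath, population_summary = spath,
                   nca_log = lpath)
  }

  artifacts <- .stamp(config, out_dir, artifacts)
  invisible(list(status = 0L, artifacts = artifacts))
}

#' Run the method-validation battery on synthetic batches
#'
#' Composes the validation checks around a fitted calibration line:
#' linearity (weighted r^2), intra-day QC per day and pooled inter-day QC at
#' the configured levels, LOQ acceptance on seven replicates at the lowest
#' level, and short-term/post-treatment stability. QC responses are
#' simulated from the true line of `cal` with the configured proportional
#' noise.
#'
#' @param fit A [fit_calibration()] result used for back-calculation.
#' @param cal Calibration block of a run config (see
#'   [default_run_config()]).
#' @param seed Integer seed for the synthetic QC/stability responses.
#' @return List with `table` (rows in detected-concentration / RSD% /
#'   accuracy% layout), `text` (human-readable report lines) and `all_pass`.
#' @export
validate_method <- function(fit, cal = default_run_config()$calibration,
                            seed = 1L) {
  set.seed(seed)
  sim_resp <- function(nominal, n, cv)
    cal$slope * nominal + cal$intercept +
      stats::rnorm(n, 0, cv * cal$slope * nominal)
  rows <- list(); lines <- character(0); pass <- logical(0)
  lines <- c(lines, sprintf("Calibration: Y = %.4fX + %.4f, weighted r^2 = %.5f (%s)",
                            fit$slope, fit$intercept, fit$r_squared, fit$weighting))
  pass <- c(pass, linearity = fit$r_squared > 0.99)
  for (nominal in as.numeric(cal$qc_levels)) {
    day_evals <- lapply(seq_len(cal$qc_days), function(d) {
      evaluate_qc(fit, sim_resp(nominal, cal$qc_replicates, cal$qc_noise_cv),
                  nominal, scope = sprintf("day-%d", d))
    })
    pooled <- evaluate_qc(fit,
                          unlist(lapply(seq_len(cal$qc_days), function(d)
                            sim_resp(nominal, cal$qc_replicates, cal$qc_noise_cv))),
                          nominal, scope = "inter-day")
    for (ev in c(day_evals, list(pooled))) {
      rows[[length(rows) + 1L]] <- as.data.frame(ev)
      ok <- ev$rsd_pct <= cal$rsd_max &&
        ev$accuracy_pct >= cal$accuracy_bounds[1] &&
        ev$accuracy_pct <= cal$accuracy_bounds[2]
      pass <- c(pass, ok)
      lines <- c(lines, sprintf(
        "QC %s @ %g ng/mL: Dect. Conc. %.2f, RSD %.2f%%, Accu. %.1f%% -> %s",
        ev$scope, nominal, ev$detected_mean, ev$rsd_pct, ev$accuracy_pct,
        if (ok) "PASS" else "FAIL"))
    }
  }
  loq_level <- min(as.numeric(cal$levels))
  loq_eval <- evaluate_qc(fit, sim_resp(loq_level, cal$loq_replicates,
                                        cal$loq_noise_cv),
                          loq_level, scope = "LOQ")
  rows[[length(rows) + 1L]] <- as.data.frame(loq_eval)
  loq <- check_loq_acceptance(loq_eval, min_n = cal$loq_replicates)
  pass <- c(pass, loq$pass)
  lines <- c(lines, sprintf("LOQ @ %g ng/mL (n = %d): RSD %.2f%%, Accu. %.1f%% -> %s",
                            loq_level, loq_eval$n, loq_eval$rsd_pct,
                            loq_eval$accuracy_pct,
                            if (loq$pass) "PASS" else paste("FAIL:", paste(loq$reasons, collapse = "; "))))
  for (cond in c("short-term", "post-treatment")) {
    for (nominal in as.numeric(cal$qc_levels)) {
      measured <- back_calculate(fit, sim_resp(nominal, cal$qc_replicates,
                                               cal$loq_noise_cv))
      st <- assess_stability(measured, nominal, cond)
      pass <- c(pass, st$pass)
      lines <- c(lines, sprintf("Stability %s @ %g ng/mL: deviation %+.2f%% -> %s",
                                cond, nominal, st$deviation_pct,
                                if (st$pass) "PASS" else "FAIL"))
    }
  }
  list(table = do.call(rbind, rows), text = lines, all_pass = all(pass))
}
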