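#' Write concentration-time profiles to CSV
#'
#' One row per sample with header
#' `subject_id,dose_mg,time_h,conc_ng_ml,blq`; censored samples have an
#' empty concentration field and `blq = TRUE`.
#'
#' @param profiles A [pk_profile()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "pk_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read concentration-time profiles from CSV
#'
#' Expects the header written by [write_profiles()]. Rows are validated and
#' sorted by time within subject; malformed rows are reported with their
#' line numbers. A quantifiable concentration below `lloq` with
#' `blq = FALSE` triggers a validation warning (the row is kept).
#'
#' @param path CSV path.
#' @param lloq Optional LLOQ (ng/mL) for consistency warnings.
#' @return Named list of [pk_profile()] objects.
#' @export
read_profiles <- function(path, lloq = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "dose_mg", "time_h", "conc_ng_ml", "blq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  df$blq <- as.logical(df$blq)
  df$time_h <- suppressWarnings(as.numeric(df$time_h))
  df$conc_ng_ml <- suppressWarnings(as.numeric(df$conc_ng_ml))
  bad <- which(is.na(df$time_h) | df$time_h < 0 | is.na(df$blq) |
                 (!is.na(df$conc_ng_ml) & df$conc_ng_ml < 0))
  if (length(bad))
    stop("malformed rows (negative or unparseable fields) at lines: ",
         paste(bad + 1L, collapse = ", "))
  if (!is.null(lloq)) {
    susp <- which(!df$blq & !is.na(df$conc_ng_ml) & df$conc_ng_ml < lloq)
    if (length(susp))
      warning("rows with concentration below LLOQ but blq = FALSE at lines: ",
              paste(susp + 1L, collapse = ", "))
  }
  ids <- unique(df$subject_id)
  profiles <- lapply(ids, function(id) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    if (any(duplicated(sub$time_h)))
      stop("duplicate sampling times for subject ", id)
    pk_profile(id, sub$dose_mg[1L], sub$time_h, sub$conc_ng_ml, sub$blq)
  })
  names(profiles) <- ids
  profiles
}

#' Write a calibration/QC batch to CSV
#'
#' Header `level_ng_ml,replicate,response`, with optional `day` and `role`
#' columns (role in standard/qc/stability) for runsheets carrying several
#' sample kinds.
#'
#' @param batch A [calibration_batch()] (extra columns are preserved).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_batch <- function(batch, path) {
  df <- as.data.frame(batch)
  names(df)[names(df) == "level"] <- "level_ng_ml"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration/QC runsheet from CSV
#'
#' @param path CSV with header `level_ng_ml,replicate,response` and optional
#'   `day`/`role` columns.
#' @param role If given and a `role` column exists, keep only matching rows.
#' @return A [calibration_batch()]; extra columns are carried along.
#' @export
read_calibration_batch <- function(path, role = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("level_ng_ml", "replicate", "response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  if (!is.null(role) && "role" %in% names(df)) df <- df[df$role == role, , drop = FALSE]
  batch <- calibration_batch(df$level_ng_ml, df$response, df$replicate)
  extra <- setdiff(names(df), required)
  for (col in extra) batch[[col]] <- df[[col]][order(df$level_ng_ml, df$replicate)]
  batch
}

#' Read a run configuration from YAML or JSON
#'
#' The configuration mirrors [run_pipeline()]'s arguments: a `mode`, paths,
#' a `population` block ([population_config()] fields), a `calibration`
#' block (`levels`, `weighting`, `noise_cv`, `slope`, `intercept`) and an
#' `nca` block. Unspecified fields take the package defaults (the standard
#' seven levels 7.5-500 ng/mL, LLOQ 7.5 ng/mL, the 0-24 h schedule, dose
#' 100 mg, 1/x weighting, 80-120%/20%/+-15% acceptance bounds).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format: .", ext))
  if (!is.list(cfg)) stop("config must be a mapping/object")
  cfg
}

#' Write a run configuration to YAML or JSON
#'
#' @param config Named list, as from [read_run_config()].
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(config, path),
         json = jsonlite::write_json(config, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         stop("unsupported config format: .", ext))
  invisible(path)
}
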