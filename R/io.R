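#' Write a trial log as CSV
#'
#' Columns `run, trial, intensity, correct, seen, step_size, boundary,
#' cwir_current`; logical fields are encoded 0/1 and intensities are written
#' with full precision so the round-trip through [read_trial_log()] is
#' lossless. Columns a method does not produce (e.g. `boundary` for
#' baselines) are written as empty fields.
#'
#' @param log A `calibration` object or its `log` data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trial_log <- function(log, path) {
  if (inherits(log, "calibration")) log <- log$log
  cols <- c("run", "trial", "intensity", "correct", "seen",
            "step_size", "boundary", "cwir_current")
  n <- NROW(log)
  if (n == 0) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  out <- data.frame(row.names = seq_len(n))
  for (col in cols) {
    v <- if (!is.null(log) && col %in% names(log)) log[[col]] else rep(NA, n)
    out[[col]] <- if (is.logical(v)) {
      as.integer(v)
    } else if (is.numeric(v)) {
      formatC(v, format = "g", digits = 17)
    } else v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trial log written by [write_trial_log()]
#'
#' Validates every row and reports the 1-based file line of the first
#' malformed one. The 0/1 `correct`/`seen` fields are parsed back to
#' logicals.
#'
#' @param path CSV file path.
#' @return Data frame with the trial-log columns.
#' @export
read_trial_log <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  need <- c("run", "trial", "intensity", "correct")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("trial log is missing columns: ", paste(missing, collapse = ", "))
  parse_num <- function(col, required = TRUE) {
    raw <- tab[[col]]
    if (is.null(raw)) return(rep(NA_real_, nrow(tab)))
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & nzchar(raw))
    if (length(bad))
      stop(sprintf("malformed value '%s' in column '%s' at line %d of %s",
                   raw[bad[1]], col, bad[1] + 1L, path))
    if (required && anyNA(v))
      stop(sprintf("missing value in column '%s' at line %d of %s",
                   col, which(is.na(v))[1] + 1L, path))
    v
  }
  parse_bool <- function(col, required = TRUE) {
    v <- parse_num(col, required)
    ok <- is.na(v) | v %in% c(0, 1)
    if (!all(ok))
      stop(sprintf("column '%s' must be 0/1; offending line %d of %s",
                   col, which(!ok)[1] + 1L, path))
    v == 1
  }
  data.frame(run = as.integer(parse_num("run")),
             trial = as.integer(parse_num("trial")),
             intensity = parse_num("intensity"),
             correct = parse_bool("correct"),
             seen = parse_bool("seen", required = FALSE),
             step_size = parse_num("step_size", required = FALSE),
             boundary = parse_num("boundary", required = FALSE),
             cwir_current = as.integer(parse_num("cwir_current", required = FALSE)))
}

scale_to_list <- function(scale) {
  out <- list(minimum = scale$minimum, maximum = scale$maximum)
  if (!is.null(scale$quantum)) out$quantum <- scale$quantum
  out
}

scale_from_list <- function(x) {
  x <- x %||% list()
  intensity_scale(x$minimum %||% 0, x$maximum %||% 200, x$quantum)
}

config_fields <- list(
  step = c("scale", "initial_step", "step_decrement", "min_step",
           "trials_per_run", "n_runs", "use_subjective", "paired_trial_mode",
           "alpha_base", "step_decrease_trigger"),
  baseline = c("method", "scale", "trials", "step", "step_decrement",
               "min_step", "max_step", "wald_limit", "target_p", "prior_mean",
               "prior_sd", "assumed_theta2", "assumed_lapse", "grid_n",
               "asa_c", "threshold_estimator", "final_batch"),
  population = c("theta1_mean", "theta1_sd", "theta2_mean", "theta2_sd",
                 "subj_theta_mean", "subj_theta_sd", "subj_sigma_mean",
                 "subj_sigma_sd", "n_participants", "lapse"))

#' Serialise a configuration to YAML or JSON
#'
#' @param config A [step_config()], [baseline_config()] or
#'   [population_spec()].
#' @param path Output path; the extension (`.yaml`/`.yml` or `.json`)
#'   selects the format.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  kind <- if (inherits(config, "step_config")) "step"
          else if (inherits(config, "baseline_config")) "baseline"
          else if (inherits(config, "population_spec")) "population"
          else stop("unsupported configuration object")
  x <- unclass(config)
  if (!is.null(x$scale)) x$scale <- scale_to_list(x$scale)
  x <- c(list(kind = kind), x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Load and validate a configuration file
#'
#' Reads a YAML or JSON configuration and returns the corresponding object
#' with defaults filled in. The file may state its `kind` (`step`,
#' `baseline` or `population`) explicitly; otherwise it is inferred from the
#' keys present (`method` implies baseline, `n_participants` implies
#' population, anything else is a STEP config). Unknown keys are rejected by
#' name.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A [step_config()], [baseline_config()] or [population_spec()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(x)) x <- list()
  kind <- x$kind %||% {
    if (!is.null(x$method) && !identical(x$method, "step")) "baseline"
    else if (!is.null(x$n_participants) ||
             any(grepl("_mean$|_sd$", names(x)))) "population"
    else "step"
  }
  x$kind <- NULL
  if (identical(x$method, "step")) x$method <- NULL
  if (!kind %in% names(config_fields)) stop("unknown config kind: ", kind)
  unknown <- setdiff(names(x), config_fields[[kind]])
  if (length(unknown))
    stop("unknown ", kind, " config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(x$scale)) x$scale <- scale_from_list(as.list(x$scale))
  switch(kind,
         step = do.call(step_config, x),
         baseline = do.call(baseline_config, x),
         population = do.call(population_spec, x))
}

#' Write a run manifest
#'
#' Records what produced a set of output files: the configuration snapshot,
#' the master seed, the package version, a timestamp and the output paths.
#' Every referenced output must exist.
#'
#' @param path Manifest path (JSON).
#' @param config Configuration object used for the run (may be `NULL`).
#' @param seed Master seed.
#' @param outputs Character vector of produced file paths.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, config, seed, outputs) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("manifest refers to missing outputs: ", paste(missing, collapse = ", "))
  snapshot <- if (is.null(config)) NULL else {
    x <- unclass(config)
    if (!is.null(x$scale)) x$scale <- scale_to_list(x$scale)
    x
  }
  manifest <- list(
    package = "stepcalib",
    version = as.character(utils::packageVersion("stepcalib")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = snapshot,
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
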