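#' Construct a calibration result
#'
#' Shared container returned by [step_calibrate()] and the baseline
#' calibration methods.
#'
#' @param method Method label ("step", "staircase", "pest", "quest", "asa").
#' @param final_threshold Final threshold estimate.
#' @param run_thresholds Per-run estimates (length 1 for single-run methods).
#' @param log Trial log data frame.
#' @param config The configuration object used.
#' @param extra Named list of method-specific extras.
#' @param class Additional S3 class prepended to `"calibration"`.
#' @return An object of class `calibration`.
#' @keywords internal
#' @export
new_calibration <- function(method, final_threshold, run_thresholds, log,
                            config, extra = list(), class = character()) {
  structure(c(list(method = method,
                   final_threshold = final_threshold,
                   run_thresholds = run_thresholds,
                   log = log,
                   config = config),
              extra),
            class = c(class, "calibration"))
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("%s calibration\n", toupper(x$method)))
  if (length(x$run_thresholds) > 1)
    cat("  run thresholds:", paste(signif(x$run_thresholds, 6), collapse = ", "), "\n")
  cat(sprintf("  final threshold: %s\n",
              if (is.na(x$final_threshold)) "NA" else signif(x$final_threshold, 6)))
  if (!is.null(x$log))
    cat(sprintf("  trials: %d\n", nrow(x$log)))
  if (isTRUE(x$aborted)) cat("  (aborted before completion)\n")
  invisible(x)
}

#' @export
coef.calibration <- function(object, ...) {
  c(threshold = object$final_threshold)
}

#' @export
summary.calibration <- function(object, ...) {
  log <- object$log
  out <- list(
    method = object$method,
    final_threshold = object$final_threshold,
    run_thresholds = object$run_thresholds,
    n_trials = if (is.null(log)) 0L else nrow(log),
    prop_correct = if (is.null(log)) NA_real_ else mean(log$correct),
    prop_seen = if (is.null(log) || is.null(log$seen)) NA_real_ else mean(log$seen),
    aborted = isTRUE(object$aborted))
  class(out) <- "summary.calibration"
  out
}

#' @export
print.summary.calibration <- function(x, ...) {
  cat(sprintf("%s calibration: %d trials, %.1f%% correct",
              toupper(x$method), x$n_trials, 100 * x$prop_correct))
  if (!is.na(x$prop_seen))
    cat(sprintf(", %.1f%% seen", 100 * x$prop_seen))
  cat("\n")
  if (length(x$run_thresholds) > 1)
    cat("  run thresholds:", paste(signif(x$run_thresholds, 6), collapse = ", "), "\n")
  cat("  final threshold:", signif(x$final_threshold, 6), "\n")
  if (x$aborted) cat("  aborted before completion\n")
  invisible(x)
}

#' Plot the intensity trace of a calibration
#'
#' Intensity per trial (per run for multi-run methods), with the boundary
#' trajectory when available and the final threshold as a horizontal line.
#'
#' @param x A `calibration` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.calibration <- function(x, ...) {
  log <- x$log
  if (is.null(log) || nrow(log) == 0) stop("no trials to plot")
  idx <- seq_len(nrow(log))
  graphics::plot(idx, log$intensity, type = "s",
                 xlab = "trial", ylab = "intensity",
                 main = sprintf("%s calibration", toupper(x$method)), ...)
  if (!is.null(log$boundary))
    graphics::lines(idx, log$boundary, lty = 3, col = "grey40")
  if (!is.null(log$run) && length(unique(log$run)) > 1) {
    breaks <- which(diff(log$run) != 0)
    graphics::abline(v = breaks + 0.5, col = "grey80")
  }
  if (!is.na(x$final_threshold))
    graphics::abline(h = x$final_threshold, col = 2, lty = 2)
  invisible(x)
}
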