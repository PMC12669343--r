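#' Baseline calibration configuration
#'
#' Configuration for the reference methods STEP is benchmarked against. All
#' baselines start at the scale maximum, respect the same clamping contract
#' as STEP, and run a single pass of `trials` trials (156 by default, the
#' same budget as a two-run STEP calibration).
#'
#' Method-specific parameters:
#' \describe{
#'   \item{staircase}{1-up 1-down with step `step`, optionally shrinking by
#'     `step_decrement` per reversal down to `min_step`; threshold per
#'     `threshold_estimator` (`mean_of_reversals`, `last_intensity`, or
#'     `second_highest_final_batch` over the last `final_batch` trials).}
#'   \item{pest}{Wald sequential test at `target_p` with deviation limit
#'     `wald_limit`; the step halves on reversals, doubles from the third
#'     same-direction step (capped at `max_step`), and never drops below
#'     `min_step`. Threshold: final intensity.}
#'   \item{quest}{Gridded Bayesian posterior over the threshold, defined -
#'     as is conventional for QUEST - at the criterion performance level
#'     `target_p` of an assumed two-part Weibull template with rise rate
#'     `assumed_theta2` and lapse `assumed_lapse`; normal prior
#'     (`prior_mean`, `prior_sd`), each trial placed at the posterior mean.
#'     Threshold: posterior mean. `target_p` must exceed 0.5 - at exactly
#'     0.5 the criterion level does not identify a unique intensity on the
#'     flat chance branch of the template.}
#'   \item{asa}{Kesten-accelerated stochastic approximation
#'     `x <- x - c/(2 + m) * (z - phi)` with `z` the 0/1 response, `phi`
#'     the target proportion correct (`target_p`) and `m` the number of
#'     update-direction reversals so far. Threshold: final intensity.}
#' }
#'
#' @param method One of `"staircase"`, `"pest"`, `"quest"`, `"asa"`.
#' @param scale An [intensity_scale()].
#' @param trials Trial budget (default 156).
#' @param step,step_decrement,min_step Staircase/PEST step parameters.
#' @param max_step PEST step ceiling.
#' @param wald_limit PEST Wald deviation limit (in trials).
#' @param target_p Target proportion correct for PEST/QUEST/ASA, in (0.5, 1).
#' @param prior_mean,prior_sd QUEST prior over the threshold (defaults:
#'   mid-scale mean, quarter-range sd).
#' @param assumed_theta2,assumed_lapse QUEST response template.
#' @param grid_n QUEST posterior grid resolution.
#' @param asa_c ASA gain constant `c`.
#' @param threshold_estimator Staircase estimator (see above).
#' @param final_batch Batch length for `second_highest_final_batch`.
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(method = c("staircase", "pest", "quest", "asa"),
                            scale = intensity_scale(0, 200),
                            trials = 156,
                            step = 8,
                            step_decrement = 0,
                            min_step = 1,
                            max_step = 64,
                            wald_limit = 1,
                            target_p = 0.62,
                            prior_mean = NULL,
                            prior_sd = NULL,
                            assumed_theta2 = 20,
                            assumed_lapse = 0.02,
                            grid_n = 201,
                            asa_c = 40,
                            threshold_estimator = c("mean_of_reversals",
                                                    "last_intensity",
                                                    "second_highest_final_batch"),
                            final_batch = 10) {
  method <- match.arg(method)
  threshold_estimator <- match.arg(threshold_estimator)
  stopifnot(inherits(scale, "intensity_scale"))
  if (trials < 0) stop("'trials' must be >= 0")
  if (method %in% c("pest", "quest", "asa")) {
    if (target_p <= 0.5 || target_p >= 1) {
      if (method == "quest" && target_p == 0.5)
        stop("QUEST cannot target exactly 0.5: below the threshold the ",
             "assumed curve is flat at chance, so no placement is defined; ",
             "choose target_p in (0.5, 1)")
      stop("'target_p' must lie in (0.5, 1)")
    }
  }
  if (is.null(prior_mean)) prior_mean <- (scale$minimum + scale$maximum) / 2
  if (is.null(prior_sd)) prior_sd <- (scale$maximum - scale$minimum) / 4
  structure(list(method = method, scale = scale, trials = as.integer(trials),
                 step = step, step_decrement = step_decrement,
                 min_step = min_step, max_step = max_step,
                 wald_limit = wald_limit, target_p = target_p,
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 assumed_theta2 = assumed_theta2,
                 assumed_lapse = assumed_lapse,
                 grid_n = as.integer(grid_n), asa_c = asa_c,
                 threshold_estimator = threshold_estimator,
                 final_batch = as.integer(final_batch)),
            class = "baseline_config")
}

#' @export
print.baseline_config <- function(x, ...) {
  cat(sprintf("Baseline config: %s, %d trials on [%g, %g]\n",
              x$method, x$trials, x$scale$minimum, x$scale$maximum))
  invisible(x)
}

clamp_scale <- function(x, scale) clamp(x, scale$minimum, scale$maximum)

#' 1-up 1-down staircase calibration
#'
#' Classic transformed staircase: a correct response lowers the intensity by
#' the current step, an incorrect one raises it. With a positive
#' `step_decrement` the step shrinks at each reversal down to `min_step`
#' (adaptive-step variant); with the default 0 the step is fixed.
#'
#' @param responder A responder function (see [participant_responder()]).
#' @param config A [baseline_config()] with `method = "staircase"`.
#' @return A `calibration` object. With the `mean_of_reversals` estimator
#'   and a log containing no reversal, the threshold is `NA` with a warning.
#' @export
staircase_calibrate <- function(responder, config = baseline_config("staircase")) {
  stopifnot(config$method == "staircase")
  x <- config$scale$maximum
  step <- config$step
  last_correct <- NA
  intensity <- correct <- numeric(0)
  reversal_at <- numeric(0)
  for (t in seq_len(config$trials)) {
    out <- responder(x)
    intensity <- c(intensity, x)
    correct <- c(correct, isTRUE(out$correct))
    if (!is.na(last_correct) && isTRUE(out$correct) != last_correct) {
      reversal_at <- c(reversal_at, x)
      if (config$step_decrement > 0)
        step <- max(step - config$step_decrement, config$min_step)
    }
    last_correct <- isTRUE(out$correct)
    x <- clamp_scale(x + ifelse(last_correct, -step, step), config$scale)
  }
  est <- switch(config$threshold_estimator,
    mean_of_reversals = {
      if (length(reversal_at) == 0L) {
        warning("no reversals occurred; mean-of-reversals estimate unavailable")
        NA_real_
      } else mean(reversal_at)
    },
    last_intensity = x,
    second_highest_final_batch = {
      nb <- min(config$final_batch, length(intensity))
      batch <- sort(utils::tail(intensity, nb), decreasing = TRUE)
      if (length(batch) >= 2) batch[2] else batch[1]
    })
  new_calibration("staircase", est, est,
                  data.frame(run = rep(1L, length(intensity)), trial = seq_along(intensity),
                             intensity = intensity,
                             correct = as.logical(correct)),
                  config,
                  extra = list(reversals = reversal_at))
}

#' PEST calibration
#'
#' Parameter Estimation by Sequential Testing. At the current level, trials
#' accumulate until the Wald sequential bound decides that performance is
#' above or below the target proportion: with `n` trials and `c` correct at
#' the level, step down when `c >= n * target_p + wald_limit` and up when
#' `c <= n * target_p - wald_limit`. On each level change the classic step
#' heuristics apply: halve the step after a direction reversal, keep it on
#' the second same-direction step, double it from the third onward (capped
#' at `max_step`, floored at `min_step`). Threshold: the final intensity.
#'
#' @inheritParams staircase_calibrate
#' @param config A [baseline_config()] with `method = "pest"`.
#' @return A `calibration` object.
#' @export
pest_calibrate <- function(responder, config = baseline_config("pest", step = 32)) {
  stopifnot(config$method == "pest")
  x <- config$scale$maximum
  step <- config$step
  n_lev <- c_lev <- 0
  last_dir <- 0L     # -1 down, +1 up
  same_dir_steps <- 0L
  intensity <- correct <- numeric(0)
  for (t in seq_len(config$trials)) {
    out <- responder(x)
    intensity <- c(intensity, x)
    correct <- c(correct, isTRUE(out$correct))
    n_lev <- n_lev + 1
    c_lev <- c_lev + isTRUE(out$correct)
    dir <- if (c_lev >= n_lev * config$target_p + config$wald_limit) {
      -1L
    } else if (c_lev <= n_lev * config$target_p - config$wald_limit) {
      1L
    } else 0L
    if (dir != 0L) {
      if (last_dir != 0L && dir != last_dir) {
        step <- max(step / 2, config$min_step)
        same_dir_steps <- 1L
      } else {
        same_dir_steps <- same_dir_steps + 1L
        if (same_dir_steps >= 3L)
          step <- min(step * 2, config$max_step)
      }
      x <- clamp_scale(x + dir * step, config$scale)
      last_dir <- dir
      n_lev <- c_lev <- 0
    }
  }
  new_calibration("pest", x, x,
                  data.frame(run = rep(1L, length(intensity)), trial = seq_along(intensity),
                             intensity = intensity,
                             correct = as.logical(correct)),
                  config)
}

#' QUEST calibration
#'
#' Bayesian adaptive estimation with a gridded posterior over the threshold.
#' Following QUEST convention the threshold parameter is the intensity at
#' the criterion performance level `target_p` of an assumed two-part Weibull
#' template (rise `assumed_theta2`, lapse `assumed_lapse`); each trial is
#' placed at the current posterior mean, and the posterior is multiplied by
#' the likelihood of the observed response and renormalised (resetting to
#' the prior in the degenerate zero-mass case). Threshold: the posterior
#' mean after the last trial - the intensity sustaining `target_p` correct,
#' which is what QUEST delivers to its users.
#'
#' @inheritParams staircase_calibrate
#' @param config A [baseline_config()] with `method = "quest"`.
#' @return A `calibration` object; `extra$posterior` holds the final grid.
#' @export
quest_calibrate <- function(responder, config = baseline_config("quest")) {
  stopifnot(config$method == "quest")
  grid <- seq(config$scale$minimum, config$scale$maximum,
              length.out = config$grid_n)
  prior <- stats::dnorm(grid, config$prior_mean, config$prior_sd)
  prior <- prior / sum(prior)
  post <- prior
  # the grid parametrises the target_p intensity; the template's chance
  # edge sits 'offset' below it
  offset <- -config$assumed_theta2 *
    log(1 - (config$target_p - 0.5) / (0.5 - config$assumed_lapse))
  p_correct_at <- function(x) {
    # template accuracy at intensity x for every candidate threshold
    d <- x - (grid - offset)
    p <- rep(0.5, length(grid))
    up <- d > 0
    p[up] <- 0.5 + (0.5 - config$assumed_lapse) *
      (1 - exp(-d[up] / config$assumed_theta2))
    p
  }
  intensity <- correct <- numeric(0)
  for (t in seq_len(config$trials)) {
    x <- clamp_scale(sum(grid * post), config$scale)
    out <- responder(x)
    intensity <- c(intensity, x)
    correct <- c(correct, isTRUE(out$correct))
    lik <- p_correct_at(x)
    if (!isTRUE(out$correct)) lik <- 1 - lik
    post <- post * lik
    s <- sum(post)
    post <- if (s <= 0 || !is.finite(s)) prior else post / s
  }
  est <- sum(grid * post)
  new_calibration("quest", est, est,
                  data.frame(run = rep(1L, length(intensity)), trial = seq_along(intensity),
                             intensity = intensity,
                             correct = as.logical(correct)),
                  config,
                  extra = list(posterior = post, grid = grid))
}

#' Kesten-accelerated stochastic approximation update
#'
#' One Robbins-Monro step with the Kesten gain schedule:
#' `x - c / (2 + m) * (z - phi)` where `z` is the binary response, `phi` the
#' target proportion correct, and `m` the number of update-direction
#' reversals accumulated so far.
#'
#' @param x Current intensity.
#' @param z Response (0/1 or logical).
#' @param phi Target proportion correct.
#' @param c_gain Gain constant.
#' @param m Number of reversals so far.
#' @return The updated (unclamped) intensity.
#' @export
asa_update <- function(x, z, phi, c_gain, m) {
  x - (c_gain / (2 + m)) * (as.numeric(z) - phi)
}

#' ASA calibration
#'
#' Accelerated stochastic approximation: applies [asa_update()] after every
#' trial, counting a reversal whenever the sign of `z - phi` flips, so the
#' effective gain `c / (2 + m)` shrinks as responses start to straddle the
#' target. Threshold: the final intensity.
#'
#' @inheritParams staircase_calibrate
#' @param config A [baseline_config()] with `method = "asa"`.
#' @return A `calibration` object.
#' @export
asa_calibrate <- function(responder, config = baseline_config("asa")) {
  stopifnot(config$method == "asa")
  x <- config$scale$maximum
  m <- 0L
  last_sign <- 0
  intensity <- correct <- numeric(0)
  for (t in seq_len(config$trials)) {
    out <- responder(x)
    intensity <- c(intensity, x)
    correct <- c(correct, isTRUE(out$correct))
    z <- as.numeric(isTRUE(out$correct))
    s <- sign(z - config$target_p)
    if (last_sign != 0 && s != 0 && s != last_sign) m <- m + 1L
    if (s != 0) last_sign <- s
    x <- clamp_scale(asa_update(x, z, config$target_p, config$asa_c, m),
                     config$scale)
  }
  new_calibration("asa", x, x,
                  data.frame(run = rep(1L, length(intensity)), trial = seq_along(intensity),
                             intensity = intensity,
                             correct = as.logical(correct)),
                  config,
                  extra = list(reversals = m))
}

#' Dispatch a calibration method by name
#'
#' @param method `"step"` or a baseline method name.
#' @param responder A responder function.
#' @param config A [step_config()] for `"step"`, else a [baseline_config()].
#' @return A `calibration` object.
#' @export
calibrate <- function(method, responder, config = NULL) {
  switch(method,
         step = step_calibrate(responder, config %||% step_config()),
         staircase = staircase_calibrate(responder, config %||% baseline_config("staircase")),
         pest = pest_calibrate(responder, config %||% baseline_config("pest", step = 32)),
         quest = quest_calibrate(responder, config %||% baseline_config("quest")),
         asa = asa_calibrate(responder, config %||% baseline_config("asa")),
         stop("unknown calibration method: ", method))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
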