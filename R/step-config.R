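#' STEP calibration configuration
#'
#' Parameters of the STEP controller. The defaults reproduce the simulation
#' configuration: ISI scale 0--200 ms, initial step 32 ms decreasing by 4 ms
#' per reversal to a 4-ms floor, 78 trials per run and two runs (156 trials
#' total), subjective-report integration enabled.
#'
#' @param scale An [intensity_scale()].
#' @param initial_step Starting step size (intensity units).
#' @param step_decrement Amount removed from the step each time the decrement
#'   trigger fires.
#' @param min_step Step-size floor; `min_step <= initial_step`.
#' @param trials_per_run Trials in each calibration run.
#' @param n_runs Number of independent runs averaged into the final
#'   threshold (default 2).
#' @param use_subjective Integrate the binary visibility report: "seen &
#'   incorrect" trials do not raise the intensity while the step size is
#'   still above its floor, and the boundary update is weighted by the seen
#'   ratio. When `FALSE` the seen ratio is replaced by a fixed 0.5.
#' @param paired_trial_mode Experiment-style pairing: intensity is updated
#'   only after every second trial, moving down if both responses were
#'   correct, up if both were incorrect, and staying put on mixed pairs.
#' @param alpha_base Base significance level of the boundary binomial test;
#'   the adaptive criterion is `alpha_base / (CWIR + 1)`.
#' @param step_decrease_trigger `"per_trial"` (default: the step follows a
#'   fixed shrinking schedule, losing `step_decrement` every trial until the
#'   floor) or `"per_reversal"` (transformed-staircase convention: it
#'   shrinks at each correct/incorrect turnaround).
#' @return An object of class `step_config`.
#' @seealso [step_calibrate()], [isi_experiment_config()],
#'   [contrast_experiment_config()]
#' @export
step_config <- function(scale = intensity_scale(0, 200),
                        initial_step = 32,
                        step_decrement = 4,
                        min_step = 4,
                        trials_per_run = 78,
                        n_runs = 2,
                        use_subjective = TRUE,
                        paired_trial_mode = FALSE,
                        alpha_base = 0.05,
                        step_decrease_trigger = c("per_trial", "per_reversal")) {
  stopifnot(inherits(scale, "intensity_scale"))
  step_decrease_trigger <- match.arg(step_decrease_trigger)
  if (min_step > initial_step) stop("'min_step' must be <= 'initial_step'")
  if (min_step <= 0 || initial_step <= 0) stop("step sizes must be > 0")
  if (step_decrement < 0) stop("'step_decrement' must be >= 0")
  if (trials_per_run < 1) stop("'trials_per_run' must be >= 1")
  if (n_runs < 1) stop("'n_runs' must be >= 1")
  if (alpha_base <= 0 || alpha_base >= 1) stop("'alpha_base' must be in (0, 1)")
  structure(list(scale = scale, initial_step = initial_step,
                 step_decrement = step_decrement, min_step = min_step,
                 trials_per_run = as.integer(trials_per_run),
                 n_runs = as.integer(n_runs),
                 use_subjective = isTRUE(use_subjective),
                 paired_trial_mode = isTRUE(paired_trial_mode),
                 alpha_base = alpha_base,
                 step_decrease_trigger = step_decrease_trigger),
            class = "step_config")
}

#' @export
print.step_config <- function(x, ...) {
  cat(sprintf(
    paste0("STEP config: scale [%g, %g], step %g -> %g (-%g, %s)\n",
           "  %d trials x %d runs, subjective %s, paired %s, alpha_base %g\n"),
    x$scale$minimum, x$scale$maximum, x$initial_step, x$min_step,
    x$step_decrement, x$step_decrease_trigger,
    x$trials_per_run, x$n_runs,
    if (x$use_subjective) "on" else "off",
    if (x$paired_trial_mode) "on" else "off", x$alpha_base))
  invisible(x)
}

#' Experiment-mode STEP presets
#'
#' `isi_experiment_config()` mirrors the metacontrast ISI calibration used
#' with a 120-Hz display: ISI 0--200 ms on an 8.33-ms frame grid, step
#' 32 ms decreasing by 8 ms to an 8-ms floor, paired-trial updates.
#' `contrast_experiment_config()` mirrors the contrast calibration: contrast
#' 0.1--1, step 0.2 decreasing by 0.05 to a 0.05 floor, per-trial updates.
#'
#' @param trials_per_run,n_runs Run structure (defaults as in [step_config()]).
#' @return A [step_config()].
#' @export
isi_experiment_config <- function(trials_per_run = 78, n_runs = 2) {
  step_config(scale = intensity_scale(0, 200, quantum = 200 / 24),
              initial_step = 32, step_decrement = 8, min_step = 8,
              trials_per_run = trials_per_run, n_runs = n_runs,
              paired_trial_mode = TRUE)
}

#' @rdname isi_experiment_config
#' @export
contrast_experiment_config <- function(trials_per_run = 78, n_runs = 2) {
  step_config(scale = intensity_scale(0.1, 1),
              initial_step = 0.2, step_decrement = 0.05, min_step = 0.05,
              trials_per_run = trials_per_run, n_runs = n_runs)
}
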