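#' Run a full STEP calibration
#'
#' Drives the complete Subliminal Threshold Estimation Procedure against a
#' responder: `n_runs` independent runs of `trials_per_run` trials each,
#' every run restarting at the scale maximum with a fresh boundary, step
#' size and CWIR bookkeeping. Within a trial the controller proposes the
#' current intensity, ingests the `(correct, seen)` outcome, updates the
#' CWIR counters, re-tests the upper boundary, adjusts the intensity, and
#' shrinks the step on reversals. The final threshold is the arithmetic mean
#' of the per-run CWIR-weighted estimates.
#'
#' @param responder A function of one argument (the proposed intensity)
#'   returning `list(correct =, seen =)`; see [participant_responder()] and
#'   [scripted_responder()].
#' @param config A [step_config()].
#' @param seed Optional integer seed applied before the first trial.
#' @return An object of class `c("step_calibration", "calibration")` with
#'   elements `final_threshold`, `run_thresholds`, `log` (one row per trial:
#'   `run, trial, intensity, correct, seen, step_size, boundary,
#'   cwir_current`), `run_flags` (per-run `no_incorrect` fallback markers)
#'   and `aborted`. If the responder throws mid-run, the calibration is
#'   aborted with a warning and the partial log is returned
#'   (`aborted = TRUE`; completed runs still contribute to the estimate).
#' @export
#' @examples
#' vp <- virtual_participant(objective_curve(25, 20), subjective_curve(25, 10))
#' set.seed(1)
#' fit <- step_calibrate(participant_responder(vp), step_config())
#' fit
#' coef(fit)
step_calibrate <- function(responder, config = step_config(), seed = NULL) {
  stopifnot(is.function(responder), inherits(config, "step_config"))
  if (!is.null(seed)) set.seed(seed)
  logs <- vector("list", config$n_runs)
  run_thresholds <- numeric(0)
  run_flags <- logical(0)
  boundary_trajectory <- vector("list", config$n_runs)
  aborted <- FALSE

  for (run in seq_len(config$n_runs)) {
    state <- init_run_state(config)
    tr_step <- tr_boundary <- numeric(0)
    tr_cwir <- integer(0)
    for (t in seq_len(config$trials_per_run)) {
      x <- state$current_intensity
      out <- tryCatch(responder(x), error = function(e) e)
      if (inherits(out, "error")) {
        warning("calibration aborted in run ", run, ", trial ", t, ": ",
                conditionMessage(out))
        aborted <- TRUE
        break
      }
      state <- record_trial(state, x, out$correct, out$seen)
      state <- update_cwir(state, out$correct)
      bt <- binomial_boundary_test(state)
      if (isTRUE(bt$significant)) state <- update_boundary(state, bt)
      reversal <- !is.na(state$last_correct) &&
        (isTRUE(out$correct) != isTRUE(state$last_correct))
      if (!config$paired_trial_mode) {
        state <- adjust_intensity(state, out$correct, out$seen)
      } else if (t %% 2L == 0L) {
        state <- adjust_intensity_paired(
          state,
          correct_pair = state$correct[(t - 1L):t],
          seen_pair = state$seen[(t - 1L):t])
      }
      state <- update_step_size(state, reversal)
      state$last_correct <- out$correct
      tr_step <- c(tr_step, state$current_step)
      tr_boundary <- c(tr_boundary, state$boundary)
      tr_cwir <- c(tr_cwir, state$cwir_current)
    }
    n <- state$n_trials
    if (n > 0L) {
      logs[[run]] <- data.frame(
        run = run, trial = seq_len(n),
        intensity = state$intensity, correct = state$correct,
        seen = state$seen, step_size = tr_step[seq_len(n)],
        boundary = tr_boundary[seq_len(n)],
        cwir_current = tr_cwir[seq_len(n)])
      boundary_trajectory[[run]] <- tr_boundary[seq_len(n)]
    }
    if (aborted) break
    est <- withCallingHandlers(
      estimate_run_threshold(state),
      warning = function(w) invokeRestart("muffleWarning"))
    run_thresholds <- c(run_thresholds, as.numeric(est))
    run_flags <- c(run_flags, isTRUE(attr(est, "no_incorrect")))
  }

  new_calibration(
    method = "step",
    final_threshold = if (length(run_thresholds)) mean(run_thresholds) else NA_real_,
    run_thresholds = run_thresholds,
    log = do.call(rbind, logs[!vapply(logs, is.null, logical(1))]),
    config = config,
    extra = list(run_flags = run_flags,
                 boundary_trajectory = boundary_trajectory,
                 aborted = aborted),
    class = "step_calibration")
}

# pair rule used in the experiment mode: intensity moves only after even
# trials - down if both correct, up if both incorrect (subjective exemption
# applies when either was seen), unchanged on mixed pairs
adjust_intensity_paired <- function(state, correct_pair, seen_pair) {
  both_correct <- all(correct_pair)
  both_incorrect <- !any(correct_pair)
  proposal <- state$current_intensity
  if (both_correct) {
    proposal <- state$current_intensity - state$current_step
  } else if (both_incorrect) {
    exempt <- any(seen_pair) && state$config$use_subjective &&
      !state$min_step_reached
    if (!exempt) proposal <- state$current_intensity + state$current_step
  }
  state$current_intensity <- confine_intensity(proposal, state)
  state
}
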