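#' Initialise the per-run state of the STEP controller
#'
#' A run starts at the maximum of the intensity scale with the upper boundary
#' set to the same value, the step at its initial size, and empty trial and
#' CWIR bookkeeping.
#'
#' @param config A [step_config()].
#' @return An object of class `step_state`: a list holding the current
#'   intensity, step size and boundary, the run's trial history, and the
#'   incorrect-sequence (CWIR) bookkeeping.
#' @export
init_run_state <- function(config) {
  stopifnot(inherits(config, "step_config"))
  structure(list(
    config = config,
    current_intensity = config$scale$maximum,
    current_step = config$initial_step,
    boundary = config$scale$maximum,
    min_step_reached = config$initial_step <= config$min_step,
    last_correct = NA,
    n_trials = 0L,
    intensity = numeric(0),
    correct = logical(0),
    seen = logical(0),
    # closed maximal runs of consecutive incorrect trials, as index ranges
    # into the trial history
    seq_start = integer(0),
    seq_end = integer(0),
    open_start = NA_integer_,
    cwir_current = 0L,        # length of the trailing incorrect streak
    cwir_closed_total = 0,    # sum of k(k+1)/2 over closed sequences
    n_boundary_updates = 0L
  ), class = "step_state")
}

#' Triangular weight of an incorrect sequence
#'
#' A run of `k` consecutive incorrect responses accumulates per-trial weights
#' 1, 2, ..., k, totalling `k * (k + 1) / 2`. Longer sequences therefore
#' carry super-linearly more weight in the threshold estimate.
#'
#' @param k Sequence length(s), non-negative integer.
#' @return `k * (k + 1) / 2`.
#' @export
sequence_weight <- function(k) {
  if (any(k < 0)) stop("'k' must be >= 0")
  k * (k + 1) / 2
}

#' Record a completed trial in the run history
#'
#' @param state A `step_state`.
#' @param intensity Intensity at which the trial was presented.
#' @param correct,seen Logical trial outcomes.
#' @return The updated state.
#' @export
record_trial <- function(state, intensity, correct, seen) {
  state$n_trials <- state$n_trials + 1L
  state$intensity <- c(state$intensity, intensity)
  state$correct <- c(state$correct, isTRUE(correct))
  state$seen <- c(state$seen, isTRUE(seen))
  state
}

#' Update the CWIR bookkeeping after a trial
#'
#' The cumulative-weighted incorrect-response counter follows the recursion
#' `CWIR(t) = 0` on a correct trial and `CWIR(t) = 1 + CWIR(t-1)` on an
#' incorrect one. A correct response closes any open incorrect sequence,
#' recording its position in the history and adding its triangular weight to
#' the run total. Call after [record_trial()].
#'
#' @param state A `step_state`.
#' @param correct Logical outcome of the trial just recorded.
#' @return The updated state.
#' @export
update_cwir <- function(state, correct) {
  if (isTRUE(correct)) {
    if (state$cwir_current > 0L) {
      state$seq_start <- c(state$seq_start, state$open_start)
      state$seq_end <- c(state$seq_end, state$open_start + state$cwir_current - 1L)
      state$cwir_closed_total <- state$cwir_closed_total +
        sequence_weight(state$cwir_current)
      state$open_start <- NA_integer_
    }
    state$cwir_current <- 0L
  } else {
    if (state$cwir_current == 0L) state$open_start <- state$n_trials
    state$cwir_current <- state$cwir_current + 1L
  }
  state
}

# running CWIR total used by the adaptive alpha: closed sequences plus the
# open trailing streak
cwir_total <- function(state) {
  state$cwir_closed_total + sequence_weight(state$cwir_current)
}

#' One-tailed binomial test against chance for the boundary rule
#'
#' Selects every trial of the current run whose intensity lies in the
#' inclusive interval `[current_intensity, boundary]` and tests whether the
#' proportion correct among them exceeds chance (0.5) with an exact
#' upper-tail binomial test. The criterion is adapted to the evidence of
#' chance-level performance accumulated so far:
#' `alpha = alpha_base / (CWIR + 1)` with CWIR the run's cumulative sequence
#' weight (the +1 guards the division when no errors have occurred).
#'
#' @param state A `step_state`.
#' @return A list with `p_value`, `alpha`, `significant`, `n_selected`,
#'   `n_correct`, `seen_ratio` and the selected trial indices. When no trial
#'   falls in the interval the test is skipped (`significant = FALSE`,
#'   `p_value = NA`).
#' @export
binomial_boundary_test <- function(state) {
  eps <- 1e-9
  sel <- which(state$intensity >= state$current_intensity - eps &
                 state$intensity <= state$boundary + eps)
  alpha <- state$config$alpha_base / (cwir_total(state) + 1)
  if (length(sel) == 0L) {
    return(list(p_value = NA_real_, alpha = alpha, significant = FALSE,
                n_selected = 0L, n_correct = 0L, seen_ratio = NA_real_,
                selected = integer(0), skipped = TRUE))
  }
  n <- length(sel)
  x <- sum(state$correct[sel])
  p <- stats::pbinom(x - 1, n, 0.5, lower.tail = FALSE)  # P(X >= x)
  list(p_value = p, alpha = alpha, significant = p < alpha,
       n_selected = n, n_correct = x,
       seen_ratio = mean(state$seen[sel]),
       selected = sel, skipped = FALSE)
}

#' Lower the dynamic upper boundary after a significant test
#'
#' The new boundary is the seen-ratio-weighted average of the old boundary
#' and the current intensity:
#' `(1 - seenRatio) * boundary + seenRatio * currentIntensity`, where the
#' seen ratio is the proportion of "seen" reports among the trials selected
#' by [binomial_boundary_test()]. When the subjective measure is disabled
#' the weight is fixed at 0.5. The boundary never increases within a run.
#'
#' @param state A `step_state`.
#' @param test The list returned by [binomial_boundary_test()].
#' @return The updated state.
#' @export
update_boundary <- function(state, test) {
  sr <- if (state$config$use_subjective) test$seen_ratio else 0.5
  state$boundary <- (1 - sr) * state$boundary + sr * state$current_intensity
  state$n_boundary_updates <- state$n_boundary_updates + 1L
  state
}

#' Adjust the stimulus intensity after a trial
#'
#' Staircase rule with the subjective exemption: a correct response lowers
#' the intensity by the current step; an incorrect response raises it -
#' unless the trial was reported seen, the subjective measure is enabled,
#' and the step size has not yet reached its floor, in which case the
#' intensity stays put (a "seen & incorrect" trial is attributed to an
#' attention lapse rather than genuine invisibility). The result is clamped
#' to `[scale$minimum, boundary]` and snapped to the grid when a quantum is
#' set.
#'
#' @param state A `step_state`.
#' @param correct,seen Logical outcomes of the trial.
#' @return The updated state.
#' @export
adjust_intensity <- function(state, correct, seen) {
  proposal <-
    if (isTRUE(correct)) {
      state$current_intensity - state$current_step
    } else if (isTRUE(seen) && state$config$use_subjective &&
               !state$min_step_reached) {
      state$current_intensity
    } else {
      state$current_intensity + state$current_step
    }
  state$current_intensity <- confine_intensity(proposal, state)
  state
}

# clamp to [scale min, boundary] and snap onto the quantum grid without
# escaping the clamped interval
confine_intensity <- function(x, state) {
  scale <- state$config$scale
  x <- clamp(x, scale$minimum, min(state$boundary, scale$maximum))
  if (!is.null(scale$quantum)) {
    x <- snap_to_grid(x, scale)
    if (x > state$boundary + 1e-9) x <- x - scale$quantum
    if (x < scale$minimum) x <- x + scale$quantum
  }
  x
}

#' Shrink the step size when the decrement trigger fires
#'
#' The step decreases by `step_decrement` down to the floor `min_step`,
#' either at each reversal (default) or on every trial, depending on
#' `step_decrease_trigger`. Reaching the floor ends the subjective-exemption
#' window of [adjust_intensity()].
#'
#' @param state A `step_state`.
#' @param reversal_occurred Logical: did the response direction just turn
#'   around (correct after incorrect or vice versa)?
#' @return The updated state.
#' @export
update_step_size <- function(state, reversal_occurred) {
  fire <- switch(state$config$step_decrease_trigger,
                 per_trial = TRUE,
                 per_reversal = isTRUE(reversal_occurred))
  if (fire) {
    state$current_step <- max(state$current_step - state$config$step_decrement,
                              state$config$min_step)
    if (state$current_step <= state$config$min_step)
      state$min_step_reached <- TRUE
  }
  state
}

#' CWIR-weighted run threshold estimate
#'
#' The run's threshold is the weighted average of the mean intensities of
#' its maximal sequences of consecutive incorrect responses, each weighted
#' by its triangular CWIR weight:
#' \deqn{\hat\theta = \sum_i CWIR_i \bar s_i / \sum_i CWIR_i.}
#' A trailing open sequence is included. A run with no incorrect response at
#' all carries no information about the threshold's location below the
#' visited range; the estimate falls back to the scale minimum with a
#' warning and attribute `no_incorrect = TRUE`.
#'
#' @param state A `step_state`.
#' @return The run threshold (numeric scalar).
#' @export
estimate_run_threshold <- function(state) {
  starts <- state$seq_start
  ends <- state$seq_end
  if (state$cwir_current > 0L) {
    starts <- c(starts, state$open_start)
    ends <- c(ends, state$open_start + state$cwir_current - 1L)
  }
  if (length(starts) == 0L) {
    warning("run contained no incorrect responses; falling back to the scale minimum")
    return(structure(state$config$scale$minimum, no_incorrect = TRUE))
  }
  k <- ends - starts + 1L
  w <- sequence_weight(k)
  m <- vapply(seq_along(starts), function(i) {
    mean(state$intensity[starts[i]:ends[i]])
  }, numeric(1))
  sum(w * m) / sum(w)
}
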