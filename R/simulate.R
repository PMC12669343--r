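#' Simulate a single 2AFC trial
#'
#' Draws the objective response by comparing a uniform(0,1) deviate against
#' the participant's true proportion correct at the given intensity, and the
#' subjective "seen" report by an independent uniform draw against the
#' visibility curve. Uses the current R random stream, so results are a pure
#' function of the stream state (seed it with [set.seed()]).
#'
#' @param participant A [virtual_participant()].
#' @param intensity Stimulus intensity (>= 0).
#' @return A list with logical elements `correct` and `seen`.
#' @export
simulate_trial <- function(participant, intensity) {
  stopifnot(inherits(participant, "virtual_participant"))
  p_correct <- objective_prob(participant$objective, intensity)
  p_seen <- subjective_prob(participant$subjective, intensity)
  list(correct = stats::runif(1) < p_correct,
       seen = stats::runif(1) < p_seen)
}

#' Simulate many trials at fixed intensities (vectorised)
#'
#' Same response rule as [simulate_trial()] but drawing the whole `correct`
#' vector before the `seen` vector, which is faster for Monte-Carlo work.
#'
#' @param participant A [virtual_participant()].
#' @param intensity Numeric vector of intensities, one per trial.
#' @return A data frame with columns `intensity`, `correct`, `seen`.
#' @export
simulate_trials <- function(participant, intensity) {
  stopifnot(inherits(participant, "virtual_participant"))
  n <- length(intensity)
  p_correct <- objective_prob(participant$objective, intensity)
  p_seen <- subjective_prob(participant$subjective, intensity)
  data.frame(intensity = intensity,
             correct = stats::runif(n) < p_correct,
             seen = stats::runif(n) < p_seen)
}

#' Turn a virtual participant into a calibration responder
#'
#' Calibration drivers ([step_calibrate()] and the baseline methods) consume
#' a responder: a function taking a proposed intensity and returning
#' `list(correct =, seen =)`. This wraps a simulated observer as such a
#' closure drawing from the current R random stream.
#'
#' @param participant A [virtual_participant()].
#' @return A responder function.
#' @export
participant_responder <- function(participant) {
  force(participant)
  function(intensity) simulate_trial(participant, intensity)
}

#' Scripted responder from fixed outcome sequences
#'
#' Replays predetermined `(correct, seen)` outcomes regardless of the
#' proposed intensity; errors when the script is exhausted. Intended for
#' tests and for replaying recorded trial logs.
#'
#' @param correct Logical vector of scripted 2AFC outcomes.
#' @param seen Logical vector of scripted visibility reports (recycled to
#'   the length of `correct`; default all `FALSE`).
#' @return A responder function.
#' @export
scripted_responder <- function(correct, seen = FALSE) {
  correct <- as.logical(correct)
  seen <- rep_len(as.logical(seen), length(correct))
  i <- 0L
  function(intensity) {
    i <<- i + 1L
    if (i > length(correct)) stop("scripted responder exhausted")
    list(correct = correct[i], seen = seen[i])
  }
}
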