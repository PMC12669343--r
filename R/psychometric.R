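#' Objective psychometric function (two-part Weibull)
#'
#' Ground-truth accuracy curve of a 2AFC observer: flat at chance (0.5) up to
#' the upper subliminal threshold `theta1`, then rising exponentially towards
#' an upper asymptote capped by the lapse rate,
#' \deqn{P(x) = 0.5 + (0.5 - \lambda)\,(1 - e^{-(x-\theta_1)/\theta_2})}
#' for \eqn{x > \theta_1} and \eqn{P(x) = 0.5} otherwise. With the default
#' lapse of 0.02 the curve spans \[0.5, 0.98\].
#'
#' @param theta1 Upper subliminal threshold (intensity units, ms for ISI;
#'   unitless for contrast). Must be >= 0.
#' @param theta2 Rise rate of performance above the threshold; must be > 0.
#' @param lapse Lapse rate: probability of a stimulus-independent error,
#'   capping the asymptote at `0.5 + (0.5 - lapse)`. Default 0.02.
#' @param guess Guess rate, fixed at 0.5 for 2AFC.
#' @return An object of class `objective_curve`.
#' @seealso [objective_prob()], [subjective_curve()]
#' @export
#' @examples
#' oc <- objective_curve(theta1 = 25, theta2 = 20)
#' objective_prob(oc, c(10, 25, 45, 2000))
objective_curve <- function(theta1, theta2, lapse = 0.02, guess = 0.5) {
  stopifnot(is.numeric(theta1), length(theta1) == 1L,
            is.numeric(theta2), length(theta2) == 1L,
            is.numeric(lapse), length(lapse) == 1L)
  if (theta1 < 0) stop("'theta1' must be >= 0")
  if (theta2 <= 0) stop("'theta2' must be > 0")
  if (lapse < 0 || lapse >= 0.5) stop("'lapse' must lie in [0, 0.5)")
  if (guess != 0.5) stop("'guess' is fixed at 0.5 for 2AFC")
  structure(list(theta1 = theta1, theta2 = theta2,
                 lapse = lapse, guess = guess),
            class = "objective_curve")
}

#' Evaluate the objective psychometric function
#'
#' @param curve An [objective_curve()].
#' @param intensity Numeric vector of stimulus intensities, all >= 0.
#' @return Probability of a correct 2AFC response at each intensity; exactly
#'   0.5 for intensities at or below `theta1`.
#' @export
objective_prob <- function(curve, intensity) {
  stopifnot(inherits(curve, "objective_curve"), is.numeric(intensity))
  if (any(intensity < 0)) stop("'intensity' must be >= 0")
  p <- rep(curve$guess, length(intensity))
  above <- intensity > curve$theta1
  if (any(above)) {
    x <- intensity[above]
    p[above] <- curve$guess + (0.5 - curve$lapse) *
      (1 - exp(-(x - curve$theta1) / curve$theta2))
  }
  p
}

#' Intensity at which the objective curve reaches a given accuracy
#'
#' Inverse of [objective_prob()] on the rising branch. Useful for placing
#' trials at a prescribed performance level (e.g. the 60%-correct point used
#' when reasoning about reversal probabilities).
#'
#' @param curve An [objective_curve()].
#' @param p Target accuracy, strictly between 0.5 and `1 - lapse + ...`
#'   i.e. within the open range of the curve.
#' @return The unique intensity with `objective_prob(curve, x) == p`.
#' @export
objective_quantile <- function(curve, p) {
  stopifnot(inherits(curve, "objective_curve"), is.numeric(p))
  hi <- curve$guess + (0.5 - curve$lapse)
  if (any(p <= curve$guess) || any(p >= hi))
    stop("'p' must lie strictly between ", curve$guess, " and ", hi)
  curve$theta1 - curve$theta2 * log(1 - (p - curve$guess) / (0.5 - curve$lapse))
}

#' Subjective visibility function (logistic)
#'
#' Ground-truth probability that a trial is reported as seen (binarized PAS
#' rating > 0), modelled as a logistic cumulative distribution
#' \deqn{P(seen \mid x) = 1 / (1 + e^{(\theta - x)/\sigma}).}
#'
#' @param theta Midpoint: the intensity reported seen on half the trials.
#' @param sigma Spread; must be > 0.
#' @return An object of class `subjective_curve`.
#' @export
subjective_curve <- function(theta, sigma) {
  stopifnot(is.numeric(theta), length(theta) == 1L,
            is.numeric(sigma), length(sigma) == 1L)
  if (sigma <= 0) stop("'sigma' must be > 0")
  structure(list(theta = theta, sigma = sigma), class = "subjective_curve")
}

#' Evaluate the subjective visibility function
#'
#' @param curve A [subjective_curve()].
#' @param intensity Numeric vector of stimulus intensities.
#' @return Probability of a "seen" report at each intensity, in (0, 1).
#' @export
subjective_prob <- function(curve, intensity) {
  stopifnot(inherits(curve, "subjective_curve"), is.numeric(intensity))
  1 / (1 + exp((curve$theta - intensity) / curve$sigma))
}

#' @export
print.objective_curve <- function(x, ...) {
  cat(sprintf(
    "Objective 2AFC curve: theta1 = %g, theta2 = %g, lapse = %g (range [0.5, %g])\n",
    x$theta1, x$theta2, x$lapse, 0.5 + (0.5 - x$lapse)))
  invisible(x)
}

#' @export
print.subjective_curve <- function(x, ...) {
  cat(sprintf("Subjective visibility curve: theta = %g, sigma = %g\n",
              x$theta, x$sigma))
  invisible(x)
}

#' Virtual participant
#'
#' Couples an objective accuracy curve and a subjective visibility curve into
#' a simulated observer. The participant's true upper subliminal threshold is
#' `objective$theta1`.
#'
#' @param objective An [objective_curve()].
#' @param subjective A [subjective_curve()].
#' @param id Optional label.
#' @return An object of class `virtual_participant`.
#' @export
virtual_participant <- function(objective, subjective, id = "vp") {
  stopifnot(inherits(objective, "objective_curve"),
            inherits(subjective, "subjective_curve"))
  structure(list(objective = objective, subjective = subjective,
                 id = as.character(id)),
            class = "virtual_participant")
}

#' @export
print.virtual_participant <- function(x, ...) {
  cat(sprintf("Virtual participant '%s' (true threshold %g)\n",
              x$id, x$objective$theta1))
  print(x$objective)
  print(x$subjective)
  invisible(x)
}

#' True threshold of a virtual participant
#' @param object A `virtual_participant`.
#' @param ... Unused.
#' @return The participant's `theta1`.
#' @export
coef.virtual_participant <- function(object, ...) {
  c(theta1 = object$objective$theta1)
}
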