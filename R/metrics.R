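#' Threshold-estimation error metrics
#'
#' Three complementary summaries of how a calibration method's estimates
#' \eqn{\hat\theta_{1i}} relate to the true upper subliminal thresholds
#' \eqn{\theta_{1i}} over a population of N participants:
#' \describe{
#'   \item{`rmse`}{\eqn{\sqrt{\frac1N \sum (\hat\theta_{1i}-\theta_{1i})^2}}
#'     - absolute deviation, in intensity units.}
#'   \item{`nrmse`}{\eqn{\sqrt{\frac1N \sum ((\hat\theta_{1i}-\theta_{1i})/\theta_{1i})^2}}
#'     - deviation relative to each true threshold (dimensionless); requires
#'     all truths > 0.}
#'   \item{`prmse`}{\eqn{\sqrt{\frac1N \sum (P(\hat\theta_{1i})-0.5)^2}}
#'     with P the participant's true objective curve - the deviation of true
#'     accuracy at the estimate from chance. Because the curve is flat at
#'     0.5 below \eqn{\theta_1}, only overestimates are penalised: PRMSE
#'     measures conscious contamination.}
#' }
#'
#' @param estimates Numeric vector of estimated thresholds.
#' @param truths Numeric vector of true thresholds (same length).
#' @param participants For [prmse()], the list of [virtual_participant()]s
#'   (or [objective_curve()]s) whose true curves evaluate the estimates.
#' @return A non-negative scalar.
#' @name error_metrics
NULL

check_lengths <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("'estimates' and 'truths' must have equal length")
  if (length(estimates) < 1) stop("need at least one (estimate, truth) pair")
}

#' @rdname error_metrics
#' @export
rmse <- function(estimates, truths) {
  check_lengths(estimates, truths)
  sqrt(mean((estimates - truths)^2))
}

#' @rdname error_metrics
#' @export
nrmse <- function(estimates, truths) {
  check_lengths(estimates, truths)
  if (any(truths == 0)) stop("NRMSE is undefined for a true threshold of 0")
  sqrt(mean(((estimates - truths) / truths)^2))
}

#' @rdname error_metrics
#' @export
prmse <- function(estimates, participants) {
  if (length(estimates) != length(participants))
    stop("'estimates' and 'participants' must have equal length")
  if (length(estimates) < 1) stop("need at least one pair")
  p_at <- vapply(seq_along(estimates), function(i) {
    curve <- participants[[i]]
    if (inherits(curve, "virtual_participant")) curve <- curve$objective
    objective_prob(curve, estimates[i])
  }, numeric(1))
  sqrt(mean((p_at - 0.5)^2))
}

#' Full per-participant error table plus the three metrics
#'
#' @param estimates Estimated thresholds.
#' @param participants List of [virtual_participant()]s.
#' @return An object of class `error_metrics`: list with `rmse`, `nrmse`,
#'   `prmse`, `n`, `n_excluded_nrmse` (truths of exactly 0, excluded from
#'   NRMSE only) and the per-participant table.
#' @export
error_metrics <- function(estimates, participants) {
  truths <- vapply(participants, function(p) p$objective$theta1, numeric(1))
  p_at <- vapply(seq_along(estimates), function(i) {
    objective_prob(participants[[i]]$objective, estimates[i])
  }, numeric(1))
  pos <- truths > 0
  out <- list(
    rmse = rmse(estimates, truths),
    nrmse = if (any(pos)) nrmse(estimates[pos], truths[pos]) else NA_real_,
    prmse = sqrt(mean((p_at - 0.5)^2)),
    n = length(estimates),
    n_excluded_nrmse = sum(!pos),
    per_participant = data.frame(
      estimate = estimates, truth = truths,
      error = estimates - truths,
      normalized_error = ifelse(pos, (estimates - truths) / truths, NA_real_),
      p_deviation = p_at - 0.5))
  class(out) <- "error_metrics"
  out
}

#' @export
print.error_metrics <- function(x, ...) {
  cat(sprintf("Error metrics over %d participants:\n", x$n))
  cat(sprintf("  RMSE  %.4f\n  NRMSE %.4f\n  PRMSE %.4f\n",
              x$rmse, x$nrmse, x$prmse))
  if (x$n_excluded_nrmse > 0)
    cat(sprintf("  (%d zero-threshold participants excluded from NRMSE)\n",
                x$n_excluded_nrmse))
  invisible(x)
}

#' Summarise an error distribution
#'
#' Median, quartiles (type-7 linear-interpolation convention) and fixed-bin
#' histogram counts of a vector of signed errors.
#'
#' @param errors Numeric vector, length >= 1.
#' @param bins Number of histogram bins.
#' @return A list with `median`, `q1`, `q3`, `iqr`, `breaks`, `counts`.
#' @export
summarize_error_distribution <- function(errors, bins = 30) {
  if (length(errors) < 1) stop("'errors' must be non-empty")
  q <- stats::quantile(errors, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  h <- graphics::hist(errors, breaks = bins, plot = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       breaks = h$breaks, counts = h$counts)
}
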