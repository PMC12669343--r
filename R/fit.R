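#' MAP fit of per-participant psychometric curves
#'
#' Fits the two-part Weibull objective curve (threshold `theta1`, rise
#' `theta2`; lapse fixed) to the 2AFC outcomes and the logistic subjective
#' curve (midpoint, spread) to the binary visibility reports of one
#' participant's constant-stimuli data, by maximum a posteriori estimation
#' under independent normal priors truncated to positive values (default
#' mean 25, sd 5 for every parameter - the same mildly informative priors
#' used for the population). This is a deliberate per-participant
#' simplification: it shares no information across participants, unlike a
#' hierarchical fit.
#'
#' With no data the prior modes (the prior means) are returned. Responses
#' concentrated on a single intensity level cannot constrain a threshold and
#' a rise rate jointly and raise an error.
#'
#' @param responses Data frame with columns `intensity`, `correct` (0/1 or
#'   logical) and either `seen` (0/1) or `pas` (0-3, binarized as seen > 0).
#' @param priors A [population_spec()] giving the prior means and sds.
#' @param lapse Fixed lapse rate of the objective curve.
#' @return A list with elements `objective` ([objective_curve()]) and
#'   `subjective` ([subjective_curve()]).
#' @export
fit_psychometric <- function(responses, priors = population_spec(),
                             lapse = 0.02) {
  stopifnot(inherits(priors, "population_spec"))
  if (is.null(responses) || nrow(responses) == 0) {
    return(list(
      objective = objective_curve(priors$theta1_mean, priors$theta2_mean,
                                  lapse = lapse),
      subjective = subjective_curve(priors$subj_theta_mean,
                                    priors$subj_sigma_mean)))
  }
  need <- c("intensity", "correct")
  if (!all(need %in% names(responses)))
    stop("'responses' needs columns intensity and correct")
  if (length(unique(responses$intensity)) < 2)
    stop("responses span a single intensity level; cannot fit a curve")
  intensity <- responses$intensity
  correct <- as.logical(as.numeric(responses$correct))
  seen <- if ("seen" %in% names(responses)) {
    as.logical(as.numeric(responses$seen))
  } else if ("pas" %in% names(responses)) {
    as.numeric(responses$pas) > 0
  } else NULL

  log_prior <- function(value, mean, sd) {
    stats::dnorm(value, mean, sd, log = TRUE)  # truncation constant drops out
  }
  nlp_obj <- function(par) {
    curve <- objective_curve(par[1], par[2], lapse = lapse)
    p <- pmin(pmax(objective_prob(curve, intensity), 1e-10), 1 - 1e-10)
    -(sum(log(p[correct])) + sum(log(1 - p[!correct])) +
        log_prior(par[1], priors$theta1_mean, priors$theta1_sd) +
        log_prior(par[2], priors$theta2_mean, priors$theta2_sd))
  }
  fit_obj <- stats::optim(c(priors$theta1_mean, priors$theta2_mean), nlp_obj,
                          method = "L-BFGS-B",
                          lower = c(1e-6, 1e-3),
                          upper = c(max(intensity) * 2, 1e4))
  objective <- objective_curve(fit_obj$par[1], fit_obj$par[2], lapse = lapse)

  subjective <- if (is.null(seen)) {
    subjective_curve(priors$subj_theta_mean, priors$subj_sigma_mean)
  } else {
    nlp_subj <- function(par) {
      curve <- subjective_curve(par[1], par[2])
      p <- pmin(pmax(subjective_prob(curve, intensity), 1e-10), 1 - 1e-10)
      -(sum(log(p[seen])) + sum(log(1 - p[!seen])) +
          log_prior(par[1], priors$subj_theta_mean, priors$subj_theta_sd) +
          log_prior(par[2], priors$subj_sigma_mean, priors$subj_sigma_sd))
    }
    fit_subj <- stats::optim(c(priors$subj_theta_mean, priors$subj_sigma_mean),
                             nlp_subj, method = "L-BFGS-B",
                             lower = c(1e-6, 1e-3),
                             upper = c(max(intensity) * 2, 1e4))
    subjective_curve(fit_subj$par[1], fit_subj$par[2])
  }
  list(objective = objective, subjective = subjective)
}

#' Read a method-of-constant-stimuli response table
#'
#' CSV with columns `participant`, `intensity`, `correct` (0/1) and `pas`
#' (0-3). PAS ratings are binarized: 0 is "not seen", anything above 0 is
#' "seen".
#'
#' @param path CSV file path.
#' @return Data frame with columns `participant`, `intensity`, `correct`
#'   (logical), `seen` (logical), `pas`.
#' @export
read_mocs_responses <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "intensity", "correct", "pas")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("MOCS file is missing columns: ", paste(missing, collapse = ", "))
  tab$correct <- as.logical(as.numeric(tab$correct))
  tab$seen <- as.numeric(tab$pas) > 0
  tab
}
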