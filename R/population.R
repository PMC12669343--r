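#' Population specification for virtual participants
#'
#' Describes the generative distribution of psychometric parameters across a
#' virtual population. Each of the four parameters (objective `theta1` and
#' `theta2`, subjective midpoint and spread) is drawn independently from a
#' normal distribution truncated to positive values. The defaults (mean 25,
#' sd 5 for every parameter) are the mildly informative priors used when
#' fitting empirical curves, reused here as the population distribution.
#'
#' @param theta1_mean,theta1_sd Mean/sd of the truncated normal for the upper
#'   subliminal threshold (intensity units).
#' @param theta2_mean,theta2_sd Mean/sd for the rise rate.
#' @param subj_theta_mean,subj_theta_sd Mean/sd for the visibility midpoint.
#' @param subj_sigma_mean,subj_sigma_sd Mean/sd for the visibility spread.
#' @param n_participants Number of virtual participants to draw.
#' @param lapse Lapse rate given to every objective curve (fixed, not sampled).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(theta1_mean = 25, theta1_sd = 5,
                            theta2_mean = 25, theta2_sd = 5,
                            subj_theta_mean = 25, subj_theta_sd = 5,
                            subj_sigma_mean = 25, subj_sigma_sd = 5,
                            n_participants = 10000, lapse = 0.02) {
  means <- c(theta1_mean, theta2_mean, subj_theta_mean, subj_sigma_mean)
  sds <- c(theta1_sd, theta2_sd, subj_theta_sd, subj_sigma_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (any(means <= 0 & sds == 0))
    stop("a non-positive mean with sd = 0 cannot yield positive parameters")
  if (n_participants < 1) stop("'n_participants' must be >= 1")
  structure(list(theta1_mean = theta1_mean, theta1_sd = theta1_sd,
                 theta2_mean = theta2_mean, theta2_sd = theta2_sd,
                 subj_theta_mean = subj_theta_mean,
                 subj_theta_sd = subj_theta_sd,
                 subj_sigma_mean = subj_sigma_mean,
                 subj_sigma_sd = subj_sigma_sd,
                 n_participants = as.integer(n_participants),
                 lapse = lapse),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    paste0("Virtual population spec: n = %d\n",
           "  theta1 ~ TN(%g, %g)  theta2 ~ TN(%g, %g)\n",
           "  subj_theta ~ TN(%g, %g)  subj_sigma ~ TN(%g, %g)  lapse = %g\n"),
    x$n_participants, x$theta1_mean, x$theta1_sd, x$theta2_mean, x$theta2_sd,
    x$subj_theta_mean, x$subj_theta_sd, x$subj_sigma_mean, x$subj_sigma_sd,
    x$lapse))
  invisible(x)
}

# inverse-CDF draw from N(mean, sd) truncated to (0, Inf); sd = 0 degenerates
# to the (positive) mean
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + (1 - lo) * stats::runif(n), mean, sd)
}

#' Mean of a normal distribution truncated to positive values
#'
#' Closed form \eqn{\mu + \sigma \phi(a)/(1-\Phi(a))} with
#' \eqn{a = -\mu/\sigma}; used as the reference expectation when checking
#' sampled populations.
#'
#' @param mean,sd Parameters of the untruncated normal.
#' @return The expectation of the truncated distribution.
#' @export
truncnorm_pos_mean <- function(mean, sd) {
  if (sd == 0) return(mean)
  a <- (0 - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

#' Sample a virtual-participant population
#'
#' Draws the four psychometric parameters of each participant independently
#' from the truncated normals of the spec. With `seed` given, repeated calls
#' return identical populations.
#'
#' @param spec A [population_spec()].
#' @param seed Optional integer seed.
#' @return A list of [virtual_participant()] objects with an attached
#'   parameter table in `attr(, "parameters")` (columns `id`, `theta1`,
#'   `theta2`, `subj_theta`, `subj_sigma`).
#' @export
sample_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_participants
  theta1 <- rtruncnorm_pos(n, spec$theta1_mean, spec$theta1_sd)
  theta2 <- rtruncnorm_pos(n, spec$theta2_mean, spec$theta2_sd)
  subj_theta <- rtruncnorm_pos(n, spec$subj_theta_mean, spec$subj_theta_sd)
  subj_sigma <- rtruncnorm_pos(n, spec$subj_sigma_mean, spec$subj_sigma_sd)
  ids <- sprintf("vp%05d", seq_len(n))
  pop <- lapply(seq_len(n), function(i) {
    virtual_participant(
      objective_curve(theta1[i], theta2[i], lapse = spec$lapse),
      subjective_curve(subj_theta[i], subj_sigma[i]),
      id = ids[i])
  })
  attr(pop, "parameters") <- data.frame(
    id = ids, theta1 = theta1, theta2 = theta2,
    subj_theta = subj_theta, subj_sigma = subj_sigma,
    stringsAsFactors = FALSE)
  class(pop) <- "virtual_population"
  pop
}

#' @export
print.virtual_population <- function(x, ...) {
  cat(sprintf("Virtual population of %d participants\n", length(x)))
  print(utils::head(attr(x, "parameters")))
  invisible(x)
}

#' Write / read a population parameter table
#'
#' Round-trips the per-participant parameters as CSV with columns
#' `id, theta1, theta2, subj_theta, subj_sigma`.
#'
#' @param population A `virtual_population` from [sample_population()].
#' @param path File path.
#' @param lapse Lapse rate used to rebuild objective curves on read.
#' @return `read_population()` returns a `virtual_population`.
#' @export
write_population <- function(population, path) {
  stopifnot(inherits(population, "virtual_population"))
  utils::write.csv(attr(population, "parameters"), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path, lapse = 0.02) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "theta1", "theta2", "subj_theta", "subj_sigma")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("population file is missing columns: ", paste(missing, collapse = ", "))
  pop <- lapply(seq_len(nrow(tab)), function(i) {
    virtual_participant(
      objective_curve(tab$theta1[i], tab$theta2[i], lapse = lapse),
      subjective_curve(tab$subj_theta[i], tab$subj_sigma[i]),
      id = tab$id[i])
  })
  attr(pop, "parameters") <- tab[need]
  class(pop) <- "virtual_population"
  pop
}
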