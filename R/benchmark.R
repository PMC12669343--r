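#' Default per-method configurations for a benchmark
#'
#' STEP runs its simulation defaults (two 78-trial runs); every baseline
#' gets the same 156-trial budget on the same scale. The staircase default
#' emulates how fixed-step staircases are deployed in unconscious-processing
#' studies: a fixed one-frame step (8 ms) with the calibrated level taken as
#' the second-highest intensity of the final batch of trials. (A
#' reversal-averaging staircase is available through
#' [baseline_config()]'s `threshold_estimator`.)
#'
#' @param scale An [intensity_scale()].
#' @param trials Total trial budget per method.
#' @return Named list of configuration objects.
#' @export
default_benchmark_configs <- function(scale = intensity_scale(0, 200),
                                      trials = 156) {
  list(
    step = step_config(scale = scale, trials_per_run = trials %/% 2, n_runs = 2),
    staircase = baseline_config("staircase", scale = scale, trials = trials,
                                step = 8,
                                threshold_estimator = "second_highest_final_batch",
                                final_batch = 10),
    pest = baseline_config("pest", scale = scale, trials = trials, step = 32),
    quest = baseline_config("quest", scale = scale, trials = trials),
    asa = baseline_config("asa", scale = scale, trials = trials))
}

#' Population-scale calibration benchmark
#'
#' Samples one virtual population, runs every requested method on every
#' participant with paired seeds (the same per-participant seed is reset
#' before each method, so methods face identical response randomness where
#' their intensity placements coincide), and scores each method with the
#' three error metrics. Runs that fail or return a non-finite estimate are
#' excluded and counted.
#'
#' @param methods Character vector from
#'   `c("step", "staircase", "pest", "quest", "asa")`.
#' @param population A [population_spec()] or an already-sampled
#'   `virtual_population`.
#' @param configs Named list of per-method configurations; defaults from
#'   [default_benchmark_configs()].
#' @param seed Master integer seed; every draw in the benchmark derives
#'   from it.
#' @return An object of class `step_benchmark`: per-method [error_metrics()],
#'   a tidy `results` data frame (`method, participant, estimate, truth,
#'   error, normalized_error, p_at_estimate`), per-method failure counts,
#'   the population parameter table and the seed.
#' @export
run_benchmark <- function(methods = c("step", "staircase", "pest", "quest", "asa"),
                          population = population_spec(n_participants = 1000),
                          configs = NULL,
                          seed = 1) {
  stopifnot(length(methods) >= 1)
  unknown <- setdiff(methods, c("step", "staircase", "pest", "quest", "asa"))
  if (length(unknown)) stop("unknown methods: ", paste(unknown, collapse = ", "))
  if (inherits(population, "population_spec")) {
    set.seed(seed)
    pop <- sample_population(population)
  } else if (inherits(population, "virtual_population")) {
    pop <- population
  } else stop("'population' must be a population_spec or virtual_population")
  n <- length(pop)
  if (is.null(configs)) configs <- default_benchmark_configs()
  set.seed(seed)
  part_seeds <- sample.int(.Machine$integer.max, n)

  rows <- list()
  metrics <- list()
  failures <- integer(0)
  for (method in methods) {
    cfg <- configs[[method]]
    est <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      set.seed(part_seeds[i])
      responder <- participant_responder(pop[[i]])
      fit <- tryCatch(
        suppressWarnings(calibrate(method, responder, cfg)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$final_threshold))
        est[i] <- fit$final_threshold
    }
    ok <- is.finite(est)
    failures[method] <- sum(!ok)
    metrics[[method]] <- error_metrics(est[ok], pop[ok])
    truths <- vapply(pop[ok], function(p) p$objective$theta1, numeric(1))
    rows[[method]] <- data.frame(
      method = method,
      participant = vapply(pop[ok], function(p) p$id, character(1)),
      estimate = est[ok], truth = truths, error = est[ok] - truths,
      normalized_error = (est[ok] - truths) / truths,
      p_at_estimate = metrics[[method]]$per_participant$p_deviation + 0.5,
      stringsAsFactors = FALSE)
  }

  structure(list(methods = methods,
                 metrics = metrics,
                 results = do.call(rbind, rows),
                 failures = failures,
                 population = attr(pop, "parameters"),
                 seed = seed),
            class = "step_benchmark")
}

#' @export
print.step_benchmark <- function(x, ...) {
  cat(sprintf("Calibration benchmark: %d participants, seed %d\n",
              nrow(x$population), x$seed))
  tab <- summary(x)
  print(tab, digits = 4)
  invisible(x)
}

#' Per-method metric table of a benchmark
#'
#' @param object A `step_benchmark`.
#' @param ... Unused.
#' @return Data frame with one row per method and columns `rmse`, `nrmse`,
#'   `prmse`, `median_error`, `iqr_error`, `failures`.
#' @export
summary.step_benchmark <- function(object, ...) {
  rows <- lapply(object$methods, function(m) {
    em <- object$metrics[[m]]
    s <- summarize_error_distribution(em$per_participant$error)
    data.frame(method = m, rmse = em$rmse, nrmse = em$nrmse,
               prmse = em$prmse, median_error = s$median,
               iqr_error = s$iqr, failures = object$failures[[m]])
  })
  do.call(rbind, rows)
}

#' Plot per-method error distributions of a benchmark
#'
#' One boxplot of signed estimation error per method, with zero marked.
#'
#' @param x A `step_benchmark`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.step_benchmark <- function(x, ...) {
  graphics::boxplot(error ~ method, data = x$results,
                    ylab = "estimation error (estimate - truth)", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Serialise a benchmark report
#'
#' Writes the per-method metrics as JSON and the tidy per-participant table
#' as CSV.
#'
#' @param benchmark A `step_benchmark`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list serialised to JSON.
#' @export
write_benchmark_report <- function(benchmark, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(benchmark, "step_benchmark"))
  tab <- summary(benchmark)
  out <- list(
    seed = benchmark$seed,
    n_participants = nrow(benchmark$population),
    methods = stats::setNames(lapply(seq_len(nrow(tab)), function(i) {
      list(rmse = tab$rmse[i], nrmse = tab$nrmse[i], prmse = tab$prmse[i],
           median_error = tab$median_error[i], iqr_error = tab$iqr_error[i],
           failures = tab$failures[i])
    }), tab$method))
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(benchmark$results, csv_path, row.names = FALSE)
  invisible(out)
}
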