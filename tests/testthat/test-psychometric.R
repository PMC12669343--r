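test_that("objective curve is flat at chance below theta1 and rises to 1 - lapse + guess", {
  oc <- objective_curve(theta1 = 25, theta2 = 20, lapse = 0.02)
  expect_identical(objective_prob(oc, c(0, 10, 24.999, 25)), rep(0.5, 4))
  # one rise constant above threshold: 0.5 + 0.48 * (1 - exp(-1))
  expect_equal(objective_prob(oc, 45), 0.5 + 0.48 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(objective_prob(oc, 45), 0.80341787, tolerance = 1e-7)
  expect_equal(objective_prob(oc, 1e6), 0.98, tolerance = 1e-12)
  expect_error(objective_prob(oc, -1), "intensity")
  expect_error(objective_curve(-1, 20), "theta1")
  expect_error(objective_curve(25, 0), "theta2")
})

test_that("objective and subjective curves are monotone with probabilities in range", {
  set.seed(101)
  xs <- seq(0, 300, by = 0.5)
  for (i in 1:25) {
    oc <- objective_curve(runif(1, 0, 100), runif(1, 1, 60),
                          lapse = runif(1, 0, 0.1))
    p <- objective_prob(oc, xs)
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0.5 & p <= 0.5 + (0.5 - oc$lapse) + 1e-12))
    sc <- subjective_curve(runif(1, 0, 100), runif(1, 0.5, 60))
    # strict behaviour probed within +/- 30 sigma of the midpoint, where
    # the logistic is representable in double precision
    zq <- subjective_prob(sc, pmax(sc$theta + sc$sigma * seq(-30, 30, by = 0.5), 0))
    expect_true(all(diff(zq) >= 0))
    expect_true(all(zq > 0 & zq < 1))
    expect_true(all(diff(subjective_prob(sc, xs)) >= 0))
  }
})

test_that("subjective curve has midpoint 0.5 and approaches a step as sigma shrinks", {
  sc <- subjective_curve(theta = 25, sigma = 10)
  expect_equal(subjective_prob(sc, 25), 0.5)
  expect_equal(subjective_prob(sc, 45), 1 / (1 + exp(-2)), tolerance = 1e-12)
  steep <- subjective_curve(25, 1e-6)
  expect_lt(subjective_prob(steep, 24.9), 1e-10)
  expect_gt(subjective_prob(steep, 25.1), 1 - 1e-10)
  expect_error(subjective_curve(25, 0), "sigma")
})

test_that("objective_quantile inverts objective_prob on the rising branch", {
  oc <- objective_curve(25, 20)
  for (p in c(0.55, 0.6, 0.75, 0.9)) {
    x <- objective_quantile(oc, p)
    expect_equal(objective_prob(oc, x), p, tolerance = 1e-10)
    expect_gt(x, oc$theta1)
  }
  expect_error(objective_quantile(oc, 0.5))
  expect_error(objective_quantile(oc, 0.99))
})

test_that("population sampling is positive, seed-reproducible, and matches the truncated-normal mean", {
  spec <- population_spec(n_participants = 10000)
  pop1 <- sample_population(spec, seed = 5)
  pop2 <- sample_population(spec, seed = 5)
  pars <- attr(pop1, "parameters")
  expect_identical(pars, attr(pop2, "parameters"))
  expect_true(all(pars$theta1 > 0 & pars$theta2 > 0 &
                    pars$subj_theta > 0 & pars$subj_sigma > 0))
  # truncation at 0 is 5 sd away, so the truncated mean is ~25.0
  expect_lt(abs(mean(pars$theta1) - truncnorm_pos_mean(25, 5)), 0.2)

  degenerate <- population_spec(theta1_sd = 0, theta2_sd = 0,
                                subj_theta_sd = 0, subj_sigma_sd = 0,
                                n_participants = 5)
  dpop <- sample_population(degenerate, seed = 1)
  dpar <- attr(dpop, "parameters")
  expect_true(all(dpar$theta1 == 25 & dpar$theta2 == 25 &
                    dpar$subj_theta == 25 & dpar$subj_sigma == 25))
  expect_error(population_spec(theta1_mean = -2, theta1_sd = 0),
               "positive")
})

test_that("population CSV round-trips through write/read", {
  pop <- sample_population(population_spec(n_participants = 8), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(attr(back, "parameters"), attr(pop, "parameters"),
               tolerance = 1e-12)
  expect_equal(back[[3]]$objective$theta1, pop[[3]]$objective$theta1,
               tolerance = 1e-12)
})

test_that("simulated responses are reproducible and converge to the true curves", {
  vp <- default_test_participant()
  set.seed(11); a <- simulate_trials(vp, rep(40, 500))
  set.seed(11); b <- simulate_trials(vp, rep(40, 500))
  expect_identical(a, b)

  n <- 10000
  # below threshold: long-run accuracy is chance
  set.seed(12)
  sub <- simulate_trials(vp, rep(10, n))
  expect_lt(abs(mean(sub$correct) - 0.5), 3 * sqrt(0.25 / n))
  # above threshold: accuracy tracks the objective curve
  p45 <- objective_prob(vp$objective, 45)
  set.seed(13)
  sup <- simulate_trials(vp, rep(45, n))
  expect_lt(abs(mean(sup$correct) - p45), 3 * sqrt(p45 * (1 - p45) / n))
  # at the subjective midpoint: half the trials are reported seen
  set.seed(14)
  mid <- simulate_trials(vp, rep(vp$subjective$theta, n))
  expect_lt(abs(mean(mid$seen) - 0.5), 3 * sqrt(0.25 / n))
})
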