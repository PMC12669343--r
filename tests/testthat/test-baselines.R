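test_that("staircase descends monotonically for an always-correct observer", {
  cfg <- baseline_config("staircase", trials = 40, step = 8,
                         threshold_estimator = "last_intensity")
  fit <- staircase_calibrate(scripted_responder(rep(TRUE, 40)), cfg)
  expect_true(all(diff(fit$log$intensity) <= 0))
  expect_equal(min(fit$log$intensity), 0)
})

test_that("mean-of-reversals averages the turnaround intensities", {
  # alternating outcomes on a 48-max scale with step 8 put the reversals at
  # 40, 48, 40, 48
  cfg <- baseline_config("staircase", scale = intensity_scale(0, 48),
                         trials = 5, step = 8)
  fit <- staircase_calibrate(scripted_responder(c(TRUE, FALSE, TRUE, FALSE, TRUE)), cfg)
  expect_equal(fit$reversals, c(40, 48, 40, 48))
  expect_equal(fit$final_threshold, 44)
  # no reversals: estimation failure signalled
  expect_warning(
    none <- staircase_calibrate(scripted_responder(rep(TRUE, 5)), cfg),
    "reversal")
  expect_true(is.na(none$final_threshold))
})

test_that("PEST follows the Wald bounds with halving and doubling step rules", {
  cfg <- baseline_config("pest", trials = 12, step = 32, wald_limit = 1,
                         target_p = 0.62)
  fit <- pest_calibrate(scripted_responder(rep(c(TRUE, FALSE), each = 6)), cfg)
  # three corrects trip the upper Wald bound twice (down 32 each); two
  # incorrects trip the lower bound: reversal halves the step to 16, the
  # second upward step keeps it, the third doubles it back to 32
  expect_equal(fit$log$intensity,
               c(200, 200, 200, 168, 168, 168, 136, 136, 152, 152, 168, 168))
  expect_equal(fit$final_threshold, 200)
})

test_that("PEST final intensity shows no systematic drift for a chance observer", {
  cfg <- baseline_config("pest", trials = 60, step = 32)
  responder <- chance_responder_factory()
  set.seed(31)
  est <- replicate(40, pest_calibrate(responder, cfg)$final_threshold)
  expect_true(all(est >= 0 & est <= 200))
  expect_gt(stats::sd(est), 0)
})

test_that("QUEST keeps a normalised posterior and shrinks it with data", {
  cfg <- baseline_config("quest", trials = 156)
  vp <- virtual_participant(objective_curve(25, 20), subjective_curve(25, 10))
  set.seed(41)
  sds <- replicate(20, {
    fit <- quest_calibrate(participant_responder(vp), cfg)
    expect_equal(sum(fit$posterior), 1, tolerance = 1e-9)
    sqrt(sum(fit$grid^2 * fit$posterior) - sum(fit$grid * fit$posterior)^2)
  })
  expect_lt(mean(sds), cfg$prior_sd)
  # the estimate concentrates near the intensity sustaining target_p correct
  set.seed(42)
  fit <- quest_calibrate(participant_responder(vp), cfg)
  target_point <- objective_quantile(vp$objective, cfg$target_p)
  expect_lt(abs(fit$final_threshold - target_point), 15)
})

test_that("QUEST with no data returns the prior mean and rejects a chance target", {
  cfg <- baseline_config("quest", trials = 0)
  fit <- quest_calibrate(function(x) stop("must not be called"), cfg)
  expect_equal(fit$final_threshold, 100, tolerance = 1e-9)
  expect_error(baseline_config("quest", target_p = 0.5), "0.5")
  expect_error(baseline_config("pest", target_p = 1.2), "target_p")
})

test_that("the Kesten update moves against the response-target difference", {
  # correct response at target 0.5 with no reversals: gain 40/2, shift 0.5
  expect_equal(asa_update(100, 1, 0.5, 40, 0), 90)
  expect_equal(asa_update(100, 0, 0.5, 40, 0), 110)
  # symmetric at phi = 0.5, so a chance observer has zero mean drift
  expect_equal(asa_update(100, 1, 0.5, 40, 2) - 100,
               -(asa_update(100, 0, 0.5, 40, 2) - 100))
  # gain strictly decreases with each reversal
  gains <- 40 / (2 + 0:5)
  expect_true(all(diff(gains) < 0))
})

test_that("ASA counts reversals and homes in on the target-p intensity", {
  cfg <- baseline_config("asa", trials = 156, asa_c = 40, target_p = 0.62)
  vp <- virtual_participant(objective_curve(25, 20), subjective_curve(25, 10))
  set.seed(51)
  fit <- asa_calibrate(participant_responder(vp), cfg)
  expect_gt(fit$reversals, 0)
  target_point <- objective_quantile(vp$objective, cfg$target_p)
  set.seed(52)
  est <- replicate(30, asa_calibrate(participant_responder(vp), cfg)$final_threshold)
  expect_lt(abs(mean(est) - target_point), 10)
})

test_that("all baselines respect the scale bounds and are seed-reproducible", {
  vp <- default_test_participant()
  for (method in c("staircase", "pest", "quest", "asa")) {
    cfg <- default_benchmark_configs()[[method]]
    cfg$trials <- 60L
    set.seed(61); a <- calibrate(method, participant_responder(vp), cfg)
    set.seed(61); b <- calibrate(method, participant_responder(vp), cfg)
    expect_identical(a$log, b$log)
    expect_identical(a$final_threshold, b$final_threshold)
    expect_true(all(a$log$intensity >= 0 & a$log$intensity <= 200))
  }
})
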