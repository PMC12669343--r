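test_that("runs start at the scale maximum with the boundary on top of it", {
  isi <- init_run_state(step_config())
  expect_equal(isi$current_intensity, 200)
  expect_equal(isi$boundary, 200)
  expect_equal(isi$current_step, 32)
  contrast <- init_run_state(contrast_experiment_config())
  expect_equal(contrast$current_intensity, 1)
  expect_equal(contrast$boundary, 1)
  expect_equal(isi$cwir_current, 0L)
  expect_length(isi$seq_start, 0)
  expect_equal(isi$n_trials, 0L)
})

test_that("sequence weights are triangular numbers", {
  expect_equal(sequence_weight(0), 0)
  expect_equal(sequence_weight(1), 1)
  expect_equal(sequence_weight(3), 6)     # 1 + 2 + 3
  expect_equal(sequence_weight(0:6), c(0, 1, 3, 6, 10, 15, 21))
  expect_error(sequence_weight(-1))
})

test_that("the CWIR counter increments on errors and closes sequences on correct trials", {
  st <- state_from_log(c(50, 46, 50, 54), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(st$cwir_current, 3L)
  st <- record_trial(st, 50, TRUE, FALSE)
  st <- update_cwir(st, TRUE)
  expect_equal(st$cwir_current, 0L)
  expect_equal(st$seq_start, 2L)
  expect_equal(st$seq_end, 4L)
  expect_equal(st$cwir_closed_total, 6)
  # a correct trial with nothing open appends nothing
  st <- record_trial(st, 46, TRUE, FALSE)
  st <- update_cwir(st, TRUE)
  expect_length(st$seq_start, 1)
})

test_that("intensity moves down on correct, up on incorrect, and freezes on seen errors", {
  cfg <- step_config()
  st <- init_run_state(cfg)
  st$current_intensity <- 100
  expect_equal(adjust_intensity(st, correct = TRUE, seen = FALSE)$current_intensity, 68)
  expect_equal(adjust_intensity(st, correct = FALSE, seen = FALSE)$current_intensity, 132)
  # seen & incorrect before the step floor: no increase
  expect_false(st$min_step_reached)
  expect_equal(adjust_intensity(st, correct = FALSE, seen = TRUE)$current_intensity, 100)
  # after the floor is reached the exemption ends
  st$min_step_reached <- TRUE
  expect_equal(adjust_intensity(st, correct = FALSE, seen = TRUE)$current_intensity, 132)
  # with the subjective measure disabled it never applies
  st2 <- init_run_state(step_config(use_subjective = FALSE))
  st2$current_intensity <- 100
  expect_equal(adjust_intensity(st2, correct = FALSE, seen = TRUE)$current_intensity, 132)
})

test_that("adjusted intensities are clamped to the boundary and snapped to the grid", {
  st <- init_run_state(step_config())
  st$current_intensity <- 190
  expect_equal(adjust_intensity(st, FALSE, FALSE)$current_intensity, 200)
  st$boundary <- 150
  st$current_intensity <- 140
  expect_equal(adjust_intensity(st, FALSE, FALSE)$current_intensity, 150)
  st$current_intensity <- 10
  expect_equal(adjust_intensity(st, TRUE, FALSE)$current_intensity, 0)
  # quantised scale: results land on the grid, half-grid ties snap downward
  qcfg <- step_config(scale = intensity_scale(0, 200, quantum = 8),
                      initial_step = 12)
  qs <- init_run_state(qcfg)
  qs$current_intensity <- 40
  expect_equal(adjust_intensity(qs, TRUE, FALSE)$current_intensity, 24)  # 28 -> tie -> down
  qs$current_intensity <- 42
  expect_equal(adjust_intensity(qs, TRUE, FALSE)$current_intensity, 32)  # 30 -> nearest
})

test_that("the step shrinks on its trigger down to the floor", {
  cfg <- step_config(initial_step = 32, step_decrement = 8, min_step = 8,
                     step_decrease_trigger = "per_reversal")
  st <- init_run_state(cfg)
  st <- update_step_size(st, reversal_occurred = TRUE)
  expect_equal(st$current_step, 24)
  st <- update_step_size(st, reversal_occurred = FALSE)
  expect_equal(st$current_step, 24)
  st$current_step <- 8
  st <- update_step_size(st, reversal_occurred = TRUE)
  expect_equal(st$current_step, 8)
  expect_true(st$min_step_reached)
  # per-trial trigger fires regardless of reversals
  pt <- init_run_state(step_config(step_decrease_trigger = "per_trial"))
  pt <- update_step_size(pt, reversal_occurred = FALSE)
  expect_equal(pt$current_step, 28)
})

test_that("the boundary binomial test matches the exact upper tail and adaptive alpha", {
  cfg <- step_config()
  st <- init_run_state(cfg)
  st$current_intensity <- 100
  for (i in 1:10) st <- record_trial(st, 150, TRUE, FALSE)
  bt <- binomial_boundary_test(st)
  expect_equal(bt$p_value, 2^-10, tolerance = 1e-12)
  expect_equal(bt$alpha, 0.05)
  expect_true(bt$significant)

  st5 <- init_run_state(cfg)
  st5$current_intensity <- 100
  for (i in 1:10) st5 <- record_trial(st5, 150, i <= 5, FALSE)
  bt5 <- binomial_boundary_test(st5)
  expect_equal(bt5$p_value, sum(choose(10, 5:10)) / 2^10, tolerance = 1e-12)
  expect_equal(bt5$p_value, 0.623046875, tolerance = 1e-9)
  expect_false(bt5$significant)

  # alpha = alpha_base / (CWIR + 1), CWIR accumulated over the run
  st$cwir_closed_total <- 16
  st$cwir_current <- 2L          # open streak adds 2 * 3 / 2 = 3
  expect_equal(binomial_boundary_test(st)$alpha, 0.05 / 20)

  # trials outside [current, boundary] are not selected; none selected -> skipped
  empty <- init_run_state(cfg)
  empty$current_intensity <- 100
  empty <- record_trial(empty, 50, TRUE, FALSE)
  expect_true(binomial_boundary_test(empty)$skipped)
})

test_that("the boundary update is the seen-ratio-weighted average", {
  cfg <- step_config()
  st <- init_run_state(cfg)
  st$boundary <- 200
  st$current_intensity <- 100
  expect_equal(update_boundary(st, list(seen_ratio = 0))$boundary, 200)
  expect_equal(update_boundary(st, list(seen_ratio = 1))$boundary, 100)
  expect_equal(update_boundary(st, list(seen_ratio = 0.5))$boundary, 150)
  ns <- init_run_state(step_config(use_subjective = FALSE))
  ns$boundary <- 200
  ns$current_intensity <- 100
  expect_equal(update_boundary(ns, list(seen_ratio = 1))$boundary, 150)
})

test_that("run thresholds are CWIR-weighted means of incorrect-sequence intensities", {
  # single sequence: its mean
  one <- state_from_log(c(40, 40), c(FALSE, TRUE))
  expect_equal(estimate_run_threshold(one), 40)
  # {k=2 at 40,44 (mean 42, w 3)} and {k=1 at 36 (w 1)}: (3*42 + 36) / 4
  two <- state_from_log(c(40, 44, 50, 36, 40), c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(estimate_run_threshold(two), 40.5)
  # constant intensity: the constant
  const <- state_from_log(rep(12, 6), c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(estimate_run_threshold(const), 12)
  # all-correct run: fallback to the scale minimum with a warning
  allc <- state_from_log(c(100, 68), c(TRUE, TRUE))
  expect_warning(est <- estimate_run_threshold(allc), "no incorrect")
  expect_equal(as.numeric(est), 0)
  expect_true(attr(est, "no_incorrect"))
})

test_that("incremental CWIR estimation matches the brute-force scan on random logs", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(5:80, 1)
    intensity <- round(runif(n, 0, 200), 2)
    correct <- runif(n) < runif(1, 0.2, 0.8)
    st <- state_from_log(intensity, correct)
    oracle <- cwir_threshold_oracle(intensity, correct)
    if (is.na(oracle)) {
      expect_warning(est <- estimate_run_threshold(st))
      expect_equal(as.numeric(est), 0)
    } else {
      expect_identical(estimate_run_threshold(st), oracle)
    }
  }
})
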