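# Independent brute-force oracle for the CWIR-weighted run threshold:
# scan a (intensity, correct) log with rle, enumerate maximal incorrect
# runs, weight each by k(k+1)/2 and average their mean intensities.
cwir_threshold_oracle <- function(intensity, correct) {
  r <- rle(correct)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  if (!any(keep)) return(NA_real_)
  k <- r$lengths[keep]
  w <- k * (k + 1) / 2
  m <- mapply(function(s, e) mean(intensity[s:e]), starts[keep], ends[keep])
  sum(w * m) / sum(w)
}

# feed an arbitrary (intensity, correct) log through the controller's
# incremental bookkeeping
state_from_log <- function(intensity, correct, config = step_config()) {
  state <- init_run_state(config)
  for (i in seq_along(intensity)) {
    state <- record_trial(state, intensity[i], correct[i], FALSE)
    state <- update_cwir(state, correct[i])
  }
  state
}

# responder whose accuracy is exactly at chance everywhere (true threshold
# at the top of the scale), with unseen reports
chance_responder_factory <- function(scale_max = 200) {
  vp <- virtual_participant(objective_curve(scale_max, 20),
                            subjective_curve(scale_max * 2, 5))
  participant_responder(vp)
}

default_test_participant <- function() {
  virtual_participant(objective_curve(25, 20), subjective_curve(25, 10),
                      id = "test")
}
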