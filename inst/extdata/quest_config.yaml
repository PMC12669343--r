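kind: baseline
method: quest
scale:
  minimum: 0.0
  maximum: 200.0
trials: 156
step: 8.0
step_decrement: 0.0
min_step: 1.0
max_step: 64.0
wald_limit: 1.0
target_p: 0.62
prior_mean: 100.0
prior_sd: 50.0
assumed_theta2: 20.0
assumed_lapse: 0.02
grid_n: 201
asa_c: 40.0
threshold_estimator: mean_of_reversals
final_batch: 10
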