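kind: step
scale:
  minimum: 0.0
  maximum: 200.0
initial_step: 32.0
step_decrement: 4.0
min_step: 4.0
trials_per_run: 78
n_runs: 2
use_subjective: yes
paired_trial_mode: no
alpha_base: 0.05
step_decrease_trigger: per_trial
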