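# Reference run configuration for voigame::run_pipeline().
# All values shown are the package defaults; delete any block to accept it.
scheme:
  h: 2100
  m: 1300
  l: 700
  cost_rate: 0.25
  intermediate_fraction: 0.5
cohort:
  n_participants: 33
  rounds_per_session: 18
  n_lottery: 3
  dictator_fraction: 0.3333333
policy:
  maximin_share: 0.1
  w_self: 1
  w_total: 0
  w_fair: 0
  temperature: 240
affect:
  baseline_mean: 46
  baseline_sd: 12
  play_effect: 12
  play_sd: 6
  disclosure_effect: 15
  disclosure_sd: 6
  zero_change_prob: 0.3077
  income_slope: -100
  p_accordance: 0.38
  attitude_concordance: 0.9
neural:
  mu: 0.1
  a: 0.15
  b: -0.1
  c: 0.4
  d: 0.25
  s: -5
  ranef_sd: 0.2
  noise_sd: 0.8
analysis:
  bootstrap_B: 2000
  conf: 0.95
  target_condition: voi
  target_rule: equality
  baseline_condition: high
  baseline_rule: inequality
  by_participant: false
seed: 1
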