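stage_frac_localized_usual:
  family: normal
  deterministic: 0.181
  low: 0.171
  high: 0.191
stage_frac_disseminated_usual:
  family: normal
  deterministic: 0.819
  low: 0.809
  high: 0.829
stage_frac_localized_screen:
  family: normal
  deterministic: 0.702
  low: 0.694
  high: 0.71
stage_frac_disseminated_screen:
  family: normal
  deterministic: 0.298
  low: 0.29
  high: 0.306
hr_overdiagnosis: 1.13
fp_rate_per_screen: 0.012
detected_to_interval_ratio: 2.8
biennial_detection_factor: 1.5
hr_death_localized: 2.68
hr_death_disseminated: 8.38
cost_usual_annual:
  family: gamma
  deterministic: 26.0
  low: 26.0
  high: 73.0
cost_screen_round:
  family: gamma
  deterministic: 189.0
  low: 147.0
  high: 232.0
cost_localized_surgical_oneoff:
  family: gamma
  deterministic: 13390.0
  low: 6337.0
  high: 20443.0
cost_localized_postsurgical_per2y:
  family: gamma
  deterministic: 19057.0
  low: 16770.0
  high: 21429.0
cost_disseminated_per2y:
  family: gamma
  deterministic: 33132.0
  low: 29357.0
  high: 34305.0
cost_false_positive:
  family: gamma
  deterministic: 2110.0
  low: 1716.0
  high: 2271.0
utility_healthy: 1.0
utility_localized:
  family: beta
  deterministic: 0.825
  low: 0.793
  high: 0.857
utility_disseminated:
  family: beta
  deterministic: 0.573
  low: 0.506
  high: 0.64
utility_false_positive:
  family: beta
  deterministic: 1.0
  low: 0.97
  high: 1.0
discount_rate_annual: 0.03
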