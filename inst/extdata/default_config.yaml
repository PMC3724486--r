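# Baseline model configuration.
# Each parameter: point value plus its sampling distribution for PSA.
# cost_nonfatal_stroke_acute and cost_post_stroke_annual are synthetic
# stand-ins (no published source value); replace with your own cost data.

p_death_is_stroke:
  value: 0.13200000000000001
  dist:
    family: beta
    params: [14, 92]
p_stroke_nonfatal:
  value: 0.80800000000000005
  dist:
    family: beta
    params: [173, 41]
p_stroke_embolic:
  value: 0.70999999999999996
  dist:
    family: beta
    params: [107, 44]
sens_mp:
  value: 0.31
  dist:
    family: beta
    params: [33, 73]
spec_mp:
  value: 0.97999999999999998
  dist:
    family: beta
    params: [179, 4]
sens_tee:
  value: 0.96999999999999997
  dist:
    family: beta
    params: [124, 4]
spec_tee:
  value: 0.80000000000000004
  dist:
    family: beta
    params: [173, 44]
rr_adaptation:
  value: 0.46000000000000002
  dist:
    family: lognormal
    params: [-0.86399999999999999, 0.39200000000000002]
p_major_adaptation:
  value: 0.027
  dist:
    family: beta
    params: [163, 5888]
excess_mortality_lt61:
  value: 0.0118
  dist:
    family: uniform
    params: [0.0082000000000000007, 0.0142000000000000008]
excess_mortality_61_70:
  value: 0.023300000000000001
  dist:
    family: uniform
    params: [0.0195, 0.027099999999999999]
excess_mortality_gt70:
  value: 0.043499999999999997
  dist:
    family: uniform
    params: [0.0349, 0.052400000000000002]
utility_post_stroke:
  value: 0.439
  dist:
    family: triangular
    params: [0.186, 0.439, 0.65300000000000002]
utility_no_complication:
  value: 1
cost_death:
  value: 2736
  dist:
    family: uniform
    params: [1368, 5471]
cost_fatal_stroke:
  value: 2736
  dist:
    family: uniform
    params: [1368, 5471]
cost_tee_device:
  value: 212
  dist:
    family: gamma
    params: [198.3991616202240778, 1.0685529024855998]
cost_surgery_base:
  value: 15628
cost_surgery_major_adaptation:
  value: 23886
cost_nonfatal_stroke_acute:
  value: 16000
cost_post_stroke_annual:
  value: 10000
discount_costs:
  value: 0.040000000000000001
discount_effects:
  value: 0.014999999999999999
mortality_calibration_reduction:
  value: 0.70999999999999996
euroscore:
  arteriopathy_or: 1.9268599325548672
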