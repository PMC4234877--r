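# "topical-like" simulated-trial preset: a large poor-prognosis NSCLC
# trial profile (670 subjects, 2038 subject-visit observations, monthly
# visits, utility mean 0.61 / SD 0.29, modest ceiling at utility = 1).
# Domain means/SDs and the correlation structure are preset choices; the
# domain-utility correlations span 0.32 (FI) to 0.69 (PF).  Correlations
# are signed: function scales and global health correlate positively with
# utility, symptom scales negatively.
name: topical-like
n_subjects: 670
n_obs: 2038
max_visits: 12
icc: 0.5
arms: [active, control]
factor_loading_utility: 0.8
utility:
  mean: 0.61
  sd: 0.29
  p_one: 0.10
  lower: -0.59
  p_zero: 0.005
  p_neg: 0.0015
domains:
  PF: {mean: 55, sd: 28, r:  0.69}
  RF: {mean: 50, sd: 32, r:  0.62}
  EF: {mean: 70, sd: 24, r:  0.48}
  CF: {mean: 75, sd: 24, r:  0.40}
  SF: {mean: 60, sd: 30, r:  0.58}
  FA: {mean: 50, sd: 27, r: -0.60}
  NV: {mean: 15, sd: 22, r: -0.38}
  PA: {mean: 35, sd: 30, r: -0.55}
  DY: {mean: 45, sd: 30, r: -0.45}
  SL: {mean: 35, sd: 32, r: -0.35}
  AP: {mean: 35, sd: 33, r: -0.42}
  CO: {mean: 25, sd: 30, r: -0.33}
  DI: {mean: 10, sd: 18, r: -0.34}
  QL: {mean: 50, sd: 24, r:  0.65}
  FI: {mean: 30, sd: 25, r: -0.32}
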