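# "soccar-like" simulated-trial preset: a smaller better-prognosis NSCLC
# trial profile (130 subjects, 1002 observations over up to 18 monthly
# visits, utility mean 0.75 / SD 0.23, 25% of responses at full health
# utility = 1).  See topical.yaml for conventions.
name: soccar-like
n_subjects: 130
n_obs: 1002
max_visits: 18
icc: 0.5
arms: [concurrent, sequential]
factor_loading_utility: 0.8
utility:
  mean: 0.75
  sd: 0.23
  p_one: 0.25
  lower: -0.59
  p_zero: 0.005
  p_neg: 0.0015
domains:
  PF: {mean: 70, sd: 24, r:  0.69}
  RF: {mean: 65, sd: 30, r:  0.62}
  EF: {mean: 78, sd: 21, r:  0.48}
  CF: {mean: 82, sd: 20, r:  0.40}
  SF: {mean: 72, sd: 27, r:  0.58}
  FA: {mean: 38, sd: 25, r: -0.60}
  NV: {mean: 10, sd: 18, r: -0.38}
  PA: {mean: 25, sd: 26, r: -0.55}
  DY: {mean: 32, sd: 27, r: -0.45}
  SL: {mean: 28, sd: 30, r: -0.35}
  AP: {mean: 22, sd: 28, r: -0.42}
  CO: {mean: 18, sd: 26, r: -0.33}
  DI: {mean: 8,  sd: 16, r: -0.34}
  QL: {mean: 62, sd: 22, r:  0.65}
  FI: {mean: 22, sd: 22, r: -0.32}
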