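# Synthetic cohort preset emulating a small, elderly, all-White European
# volunteer population with normal spirometry: n = 457, 61% women, age
# 73 +/- 5 y, height 158 +/- 9 cm (overall), weight 70 +/- 12 kg. Structural
# coefficients are SYNTHETIC package defaults calibrated to this population's
# landmark means; its surface intentionally differs from the cleveland_like
# preset so that models trained on one cohort show a "cohort effect" on the
# other, as the pooled-training workflow is meant to exercise.
name: madrid_like
"n": 457
fraction_female: 0.61
fraction_black: 0.0
age: {mean: 73.0, sd: 5.0, min: 60.0}
height:
  female: {mean: 154.0, sd: 7.0}
  male: {mean: 164.0, sd: 7.0}
weight: {mean: 70.0, sd_resid: 11.0, beta_height: 0.5}
reference: {age: 73.0, height: 158.0, weight: 70.0}
surface:
  fvc: {intercept: 1.072676, height: 0.15, age: -0.070, age2: -0.030,
        male: 0.12, black: -0.10, male_height: 0.03, weight: -0.015}
  pef: {intercept: 1.728992, height: 0.12, age: -0.060, age2: -0.040,
        male: 0.18, black: -0.08, male_height: 0.05, weight: -0.010}
ratios:
  fev1_fvc:    {base: 0.78,  age_slope: -0.010, sd: 0.030, min: 0.70, max: 0.95}
  fef25_pef:   {base: 0.857, age_slope: -0.005, sd: 0.010, min: 0.60, max: 0.97}
  fef50_fef25: {base: 0.520, age_slope: -0.005, sd: 0.010, min: 0.35, max: 0.75}
  fef75_fef50: {base: 0.200, age_slope: -0.010, sd: 0.012, min: 0.10, max: 0.55}
fev_pef: {intercept: 0.157174, slope: 0.176439, sd: 0.06, min_L: 0.05,
          max_frac: 0.24}
noise: {fvc: 0.12, pef: 0.18, aex: 0.03}
shape: 1.0
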