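# Synthetic cohort preset emulating a large, mixed-race adult US clinical
# population with normal spirometry. Demographic marginals: n = 3111, ~66%
# women, 13% Black, age 53 +/- 15 y, height 166 +/- 10 cm (overall), weight
# 82 +/- 20 kg. The structural surface coefficients below are SYNTHETIC
# package defaults (log-linear surface in 10-cm / 10-y / 10-kg units with a
# quadratic age term and a gender x height interaction), chosen so cohort
# landmark means land near the emulated population's; they are not estimates
# from any real cohort.
name: cleveland_like
"n": 3111
fraction_female: 0.66
fraction_black: 0.13
age: {mean: 53.0, sd: 15.0, min: 18.0}
height:
  female: {mean: 162.0, sd: 7.0}
  male: {mean: 174.0, sd: 7.0}
weight: {mean: 82.0, sd_resid: 18.0, beta_height: 0.6}
reference: {age: 53.0, height: 166.0, weight: 82.0}
surface:
  fvc: {intercept: 1.346112, height: 0.15, age: -0.060, age2: -0.030,
        male: 0.12, black: -0.10, male_height: 0.03, weight: -0.015}
  pef: {intercept: 1.991152, height: 0.12, age: -0.050, age2: -0.040,
        male: 0.18, black: -0.08, male_height: 0.05, weight: -0.010}
ratios:
  fev1_fvc:    {base: 0.80,  age_slope: -0.010, sd: 0.030, min: 0.70, max: 0.95}
  fef25_pef:   {base: 0.880, age_slope: -0.005, sd: 0.010, min: 0.60, max: 0.97}
  fef50_fef25: {base: 0.550, age_slope: -0.005, sd: 0.010, min: 0.35, max: 0.75}
  fef75_fef50: {base: 0.294, age_slope: -0.010, sd: 0.012, min: 0.12, max: 0.55}
fev_pef: {intercept: 0.157174, slope: 0.176439, sd: 0.06, min_L: 0.05,
          max_frac: 0.24}
noise: {fvc: 0.12, pef: 0.18, aex: 0.03}
shape: 1.0
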