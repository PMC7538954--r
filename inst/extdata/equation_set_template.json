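{
  "name": "user_equation_set_template",
  "comment": "Template for published spirometry equation sets (e.g. ECSC, NHANES III, or AEX equations by gender/race). Fill intercepts and terms from the source publication; coefficients are NOT bundled with the package. Each stratum entry predicts one target (AEX, FVC, PEF, FEV1, FEV_PEF, FEF25, FEF50, FEF75) as intercept + sum(coef * var^power) with var in {age [y], height [cm], weight [kg]}; scale 'log' means the formula yields the natural log of the target.",
  "strata": [
    {
      "gender": "female",
      "race": "white",
      "target": "AEX",
      "intercept": 0.0,
      "terms": [
        {"var": "age", "power": 1, "coef": 0.0},
        {"var": "height", "power": 1, "coef": 0.0}
      ],
      "scale": "none",
      "valid_age": [18, 95],
      "valid_height": [120, 210]
    }
  ]
}
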