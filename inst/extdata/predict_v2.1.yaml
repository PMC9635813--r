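# PREDICT v2.1 coefficient configuration, transcribed from the public
# PREDICT v2.1 source code. Prognostic-index terms are
# coefficient * (transform(covariate) - center) with fractional-polynomial
# transforms of (value + shift) / scale; categorical terms carry per-level
# offsets. Baselines are log cumulative hazards as fractional polynomials
# in time (years). The chemotherapy log-hazard-ratio is the third-generation
# regimen value.
version: "2.1"
mi:
  a: 0.0698252
  b: 34.23391957
ranges:
  age_years: [25.0, 85.0]
  size_mm: [1.0, 400.0]
  nodes: [0.0, 50.0]
strata:
  positive:
    pi_terms:
      - {covariate: age_years, scale: 10, power: -2, coefficient: 34.53642, center: 0.0287449295}
      - {covariate: age_years, scale: 10, power: -2, log_multiplier: true, coefficient: -34.20342, center: 0.0510121013}
      - {covariate: size_mm, scale: 100, power: 0, coefficient: 0.7530729, center: -1.545233938}
      - {covariate: nodes, shift: 1, scale: 10, power: 0, coefficient: 0.7060723, center: -1.387566896}
      - {covariate: grade, power: 1, coefficient: 0.746655, center: 0}
      - {covariate: detection, levels: {screening: -0.22763366, symptoms: 0.0, unknown: -0.11386683}}
      - {covariate: her2, levels: {positive: 0.2413, negative: -0.0762, unknown: 0.0}}
      - {covariate: ki67, levels: {positive: 0.14904, negative: -0.11333, unknown: 0.0}}
    baseline_breast:
      type: fp
      intercept: 0.7424402
      terms:
        - {power: -0.5, coefficient: -7.527762}
        - {power: -0.5, log_multiplier: true, coefficient: -1.812513}
      support: [0.5, 15.0]
  negative:
    pi_terms:
      - {covariate: age_years, power: 1, coefficient: 0.0089827, center: 56.3254902}
      - {covariate: size_mm, scale: 100, power: 0.5, coefficient: 2.093446, center: 0.5090456276}
      - {covariate: nodes, shift: 1, scale: 10, power: 0, coefficient: 0.6260541, center: -1.086916249}
      - {covariate: grade, levels: {"1": 0.0, "2": 1.129091, "3": 1.129091}}
      - {covariate: detection, levels: {screening: -0.22763366, symptoms: 0.0, unknown: -0.11386683}}
      - {covariate: her2, levels: {positive: 0.2413, negative: -0.0762, unknown: 0.0}}
    baseline_breast:
      type: fp
      intercept: -1.156036
      terms:
        - {power: -2, coefficient: 0.4707332}
        - {power: -1, coefficient: -3.51355}
      support: [0.5, 15.0]
baseline_other:
  type: fp
  intercept: -6.052919
  terms:
    - {power: 0, coefficient: 1.079863}
    - {power: 0.5, coefficient: 0.3255321}
  support: [0.5, 15.0]
treatments:
  hormone: -0.3857
  chemo: -0.446
  trastuzumab:
    loghr: -0.3567
    requires: {her2: positive}
  bisphosphonates:
    loghr: -0.198
    requires: {menopause: post}
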