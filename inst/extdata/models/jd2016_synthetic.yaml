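model_id: JD2016
species:
- HYP
- PIF
- EC
units:
  concentration: nM
  time: h
initial_state:
  HYP: 6.2713000000000001
  PIF: 3.60459873641147643
  EC: 2.70192306194020837
production:
  HYP:
    alpha: 0.07451366554349398
    factors:
    - members: PIF
      exponent: 1.0
  PIF:
    alpha: 1.0
    factors: []
  EC:
    alpha: 0.20000000000000001
    factors:
    - members: PIF
      exponent: 1.0
degradation:
  HYP: []
  PIF:
  - beta: 0.14999999999999999
    exponents: {}
  - beta: 0.05
    exponents:
      EC: 1.0
  EC:
  - beta: 0.25
    exponents: {}
light:
  HYP: []
  PIF:
  - gamma: -0.84999999999999998
    gate: light
    factor:
      members: PIF
      exponent: 1.0
  EC: []
design:
  model_id: JD2016
  target_species: HYP
  lost_regulator: PIF
  gamma_P: 0.0
  published_mu_range:
  - 6.2713000000000001
  - 21.41949999999999932
  parameter_source: synthetic stand-in calibrated to the published profile range
  reference:
    window_hours: 96.0
    transient_days: 0.0
    periodic: no

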