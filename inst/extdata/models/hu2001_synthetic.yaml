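model_id: HU2001
species:
- PER
- CLK_CYC
- PER_TIM
units:
  concentration: nM
  time: h
initial_state:
  PER: 0.35577187016409184
  CLK_CYC: 0.25013545707212015
  PER_TIM: 0.51823403062113893
production:
  PER:
    alpha: 1.26162471478563587
    factors:
    - members: CLK_CYC
      exponent: 1.26479125868962239
  CLK_CYC:
    alpha: 0.20000000000000001
    factors: []
  PER_TIM:
    alpha: 0.29999999999999999
    factors:
    - members: PER
      exponent: 1.0
degradation:
  PER:
  - beta: 0.52380000000000004
    exponents: {}
  - beta: 0.14999999999999999
    exponents:
      PER_TIM: 1.0
  CLK_CYC:
  - beta: 0.80000000000000004
    exponents: {}
  PER_TIM:
  - beta: 0.29999999999999999
    exponents: {}
light:
  PER: []
  CLK_CYC:
  - gamma: 1.60000000000000009
    gate: light
    factor: ~
  PER_TIM: []
design:
  model_id: HU2001
  target_species: PER
  lost_regulator: CLK_CYC
  gamma_P: 0.52380000000000004
  published_mu_range:
  - 0.34499999999999997
  - 3.89429999999999987
  parameter_source: synthetic stand-in calibrated to the published profile range
  reference:
    window_hours: 96.0
    transient_days: 2.0
    periodic: yes

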