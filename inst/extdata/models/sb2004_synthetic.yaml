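model_id: SB2004
species:
- BMAL1
- PER2_CRY
- REV
units:
  concentration: nM
  time: h
initial_state:
  BMAL1: 1.80035551210076683
  PER2_CRY: 2.19998770600507942
  REV: 2.17280017096836886
production:
  BMAL1:
    alpha: 1.65737432519663352
    factors:
    - members: PER2_CRY
      exponent: 0.84911607943505474
  PER2_CRY:
    alpha: 0.20000000000000001
    factors: []
  REV:
    alpha: 0.40000000000000002
    factors:
    - members: PER2_CRY
      exponent: 1.0
degradation:
  BMAL1:
  - beta: 1.58159999999999989
    exponents: {}
  - beta: 0.10000000000000001
    exponents:
      REV: 1.0
  PER2_CRY:
  - beta: 1.0
    exponents: {}
  REV:
  - beta: 0.40000000000000002
    exponents: {}
light:
  BMAL1: []
  PER2_CRY:
  - gamma: 2.0
    gate: dark
    factor: ~
  REV: []
design:
  model_id: SB2004
  target_species: BMAL1
  lost_regulator: PER2_CRY
  gamma_P: 1.58159999999999989
  published_mu_range:
  - 0.2626
  - 1.83170000000000011
  parameter_source: synthetic stand-in calibrated to the published profile range
  reference:
    window_hours: 96.0
    transient_days: 2.0
    periodic: yes

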