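model_id: JL2005
species:
- LHY_CCA1
- TOC1
- X
units:
  concentration: nM
  time: h
initial_state:
  LHY_CCA1: 2.34487728475239177
  TOC1: 2.24986457499642611
  X: 2.21748568570839577
production:
  LHY_CCA1:
    alpha: 2.62790777806293852
    factors:
    - members: TOC1
      exponent: 0.36616139529251779
  TOC1:
    alpha: 0.20000000000000001
    factors: []
  X:
    alpha: 0.40000000000000002
    factors:
    - members: TOC1
      exponent: 1.0
degradation:
  LHY_CCA1:
  - beta: 1.28750000000000009
    exponents: {}
  - beta: 0.10000000000000001
    exponents:
      X: 1.0
  TOC1:
  - beta: 0.80000000000000004
    exponents: {}
  X:
  - beta: 0.40000000000000002
    exponents: {}
light:
  LHY_CCA1:
  - gamma: 0.26279077780629384
    gate: light
    factor: ~
  TOC1:
  - gamma: 1.60000000000000009
    gate: dark
    factor: ~
  X: []
design:
  model_id: JL2005
  target_species: LHY_CCA1
  lost_regulator: TOC1
  gamma_P: 1.28750000000000009
  published_mu_range:
  - 1.3919999999999999
  - 2.41489999999999982
  parameter_source: synthetic stand-in calibrated to the published profile range
  reference:
    window_hours: 96.0
    transient_days: 2.0
    periodic: yes

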