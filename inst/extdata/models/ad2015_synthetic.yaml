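model_id: AD2015
species:
- FRQ
- WC1
- WCC
units:
  concentration: nM
  time: h
initial_state:
  FRQ: 0.08117184744850432
  WC1: 0.2501523791604523
  WCC: 0.34565776139313276
production:
  FRQ:
    alpha: 0.52264129552869698
    factors:
    - members: WC1
      exponent: 1.87187374400293827
  WC1:
    alpha: 0.20000000000000001
    factors: []
  WCC:
    alpha: 0.29999999999999999
    factors:
    - members: WC1
      exponent: 1.0
degradation:
  FRQ:
  - beta: 0.27489999999999998
    exponents: {}
  - beta: 0.5
    exponents:
      WCC: 1.0
  WC1:
  - beta: 0.80000000000000004
    exponents: {}
  WCC:
  - beta: 0.29999999999999999
    exponents: {}
light:
  FRQ: []
  WC1:
  - gamma: 1.80000000000000004
    gate: light
    factor: ~
  WCC: []
design:
  model_id: AD2015
  target_species: FRQ
  lost_regulator: WC1
  gamma_P: 0.27489999999999998
  published_mu_range:
  - 0.0738
  - 2.55830000000000002
  parameter_source: synthetic stand-in calibrated to the published profile range
  reference:
    window_hours: 96.0
    transient_days: 2.0
    periodic: yes

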