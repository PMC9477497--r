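# Example plantdeb run configuration.
# Any key omitted here falls back to the package default
# (see plantdeb::default_config()).
model: root_shoot
plant:
  j_CAm: 1.0        # max specific CH2O assimilation (C-mol C-mol^-1 d^-1)
  j_NAm: 0.08       # max specific N uptake (N-mol C-mol^-1 d^-1)
  eta_T: 0.95       # translocation efficiency
env:
  kind: constant
  co2: 1.0
  light: 1.0
  soil_n: 1.0
  temperature: 293.15
solver:
  t_span: [0.0, 250.0]
  record_every: 1.0
state:
  M_V_S: 1.0
  M_V_R: 1.0
seed: 1
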