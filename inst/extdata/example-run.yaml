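# Example desk-scale run configuration for the CLI front end.
model:
  chi: 0.7
  lam: 0.5
  eps_PP: 1.0
  eps_PR: 0.5
  eps_RR: 0.0
  sigma: 1.0
system:
  n_total: 192
  X: 0.25        # regulator-to-protein number ratio N_R/N_P
  rho0: 0.3
  temperature: 0.68
schedule:
  n_displacement: 500
  n_exchange: 500
  n_volume: 5
  max_translation: 0.15
  max_rotation: 0.4
  max_ln_volume_change: 0.04
run:
  n_equil: 15000
  n_collect: 30000
  sample_stride: 25
  seed: 1
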