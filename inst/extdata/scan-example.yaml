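# small density-temperature grid, real parametrisation
schema_version: 1
model:
  preset: real
state:
  rho_grid: [0.75, 0.80, 0.85, 0.90, 0.95]
  T_grid: [0.15, 0.16]
n_particles: 100
mc:
  profile: scan
  rng_seed: 7
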