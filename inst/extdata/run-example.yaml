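# single state point, MB parametrisation, quick desk run
schema_version: 1
model:
  preset: mb
state:
  rho: 0.9
  T: 0.15
n_particles: 100
mc:
  n_equil_cycles: 2000
  n_series: 4
  cycles_per_series: 2000
  rng_seed: 11
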