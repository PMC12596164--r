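# Demo run configuration for the `report` subcommand.
# Small world: 4 years, 4 clades, short genes -- finishes in seconds.
seed: 7
log_level: info
simulation:
  n_clades: 4
  founder_divergence_nt: 40
  mu: 0.0002
  generations_per_interval: 4
  years: 4
  peak_log10: 5.2
  trough_log10: 0
  effective_size_cap: 400
  trough_effective_size: 32
  sample_sizes:
    sum2009: 20
    sum2010: 12
    sum2011: 12
    sum2012: 12
abundance:
  lod: 1
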