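# Example run configuration: override any default; unknown keys are
# rejected.  See default_config() for the full schema.
model:
  n: 20          # LAHN neurons
  beta: 50       # spatial gain (rad per arena unit)
  grid_shape: [8, 8]
experiment:
  duration: 600
  seeds: [1, 2, 3, 4, 5]
analysis:
  bin_size: 0.01
  max_lag: 0.25
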