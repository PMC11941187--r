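# Long thin rod in the reference conical channel (survival-decay showcase).
channel:
  L: 15
  R0: 0.5
  RL: 0.25
particle:
  l: 7
  r: 0.05
noise:
  sigma_x: 0.05
run:
  n_rep: 100
  seed: 42
  max_steps: 20000000
analysis:
  n_bins_z: 30
  n_bins_theta: 30
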