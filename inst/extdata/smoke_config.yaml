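# Smoke-test configuration: a complete end-to-end run at toy scale
# (10 phantoms, depth-2/base-4 network, 24^3 patches, 50 iterations).
seed: 7
output_root: segvol_smoke
simulate:
  n_cases: 10
  spacing: [1.0, 1.0, 1.0]
  test_fraction: 0.2
preprocess:
  patch_size: [24, 24, 24]
network:
  depth: 2
  base_channels: 4
train:
  max_iterations: 50
  batch_size: 2
  checkpoint_every: 25
infer:
  overlap: 0.25
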