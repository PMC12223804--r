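# Nested multi-MAB configuration on the surrogate-unbinding system:
# the (rmsd, eint, dist) space is cut into outer regions along rmsd and
# a separate adaptive-binning scheme is nested in each, so leading
# walkers in one region cannot soak up all the splitting.
system:
  kind: surrogate_unbinding_2d
resampler:
  type: multimab
  outer_boundaries:
    - [0, 7.5, 10.5, .inf]
    - [-.inf, .inf]
    - [-.inf, .inf]
  schemes:
    - placement: [3, 0, 0]
      bins_per_dim: [5, 1, 1]
      direction: [1, -1, 1]
      target_per_bin: 4
    - placement: [8, 0, 0]
      bins_per_dim: [5, 1, 5]
      direction: [1, -1, 1]
      target_per_bin: 4
    - placement: [11, 0, 0]
      bins_per_dim: [1, 1, 5]
      direction: [1, -1, 1]
      target_per_bin: 4
states: default
walker_count: 40
tau: 1
iterations: 300
seed: 42
stop_state: unbound
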