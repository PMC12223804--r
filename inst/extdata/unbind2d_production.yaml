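# Production-style binless WE configuration for the built-in 2-D
# surrogate-unbinding system: 40 walkers, top/bottom N = 5 split/merge,
# three-coordinate progress score with the 0.8 backward-progress window
# on the rmsd-like coordinate. Coordinate ranges follow the usual
# ligand-unbinding setup (rmsd 0 -> 25, interaction energy 350 -> -200,
# separation distance 0 -> 10), rescaled onto the surrogate landscape.
system:
  kind: surrogate_unbinding_2d
score:
  coordinates:
    - name: rmsd
      initial: 0
      target: 25
      regions:
        - [10, 13, 0.8]
    - name: eint
      initial: 350
      target: -200
    - name: dist
      initial: 0
      target: 10
  balance: inverse_neg_log
  balance_cap: 1000
resampler:
  type: mabl
  n_split_merge: 5
states: default
walker_count: 40
tau: 1
iterations: 300
seed: 42
stop_state: unbound
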