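# Example run configuration. Omitted keys take the package defaults
# (L = 250, T = 1.5, R = 0.05, 140 nuclei, OU boundary sd 0.25).
mode: simulate
seed: 1
simulation:
  t_end: 50
  snapshot_every: 5
potential:
  adhesion_strength: 2
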