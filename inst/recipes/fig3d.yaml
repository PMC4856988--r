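name: fig3d
description: >
  Permanent loops: all beads pink and weakly bound by red factors; the
  fiber is pre-organized into 324-bead loops separated by 300 unlooped
  beads (150 unlooped at each end) by irreversible anchor bonds.
units: {sigma_nm: 30, kbp_per_bead: 3}
box_edge_nm: 3000
fibers:
  - {n_beads: 4992, pattern: uniform, uniform_color: pink,
     loops: {loop_beads: 324, gap_beads: 300, end_beads: 150}}
factors:
  - color: red
    count: 250
    affinity: {pink: 3.0}
    activation_time: 10000
duration: 60000
sample_every: 1000
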