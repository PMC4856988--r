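name: fig1a
description: >
  Toy model: 15-Mbp fiber of 5000 30-nm beads in a 3-um periodic cube with
  250 red factors (15 nM).  One bead in 20 is pink (regular spacing); red
  factors bind pink beads strongly and all other beads weakly after
  activation at 1e4 time units.
units: {sigma_nm: 30, kbp_per_bead: 3}
box_edge_nm: 3000
fibers:
  - {n_beads: 5000, pattern: regular, every: 20, color: pink, base_color: blue}
factors:
  - color: red
    count: 250
    affinity: {pink: 8.0, blue: 3.0}
    activation_time: 10000
duration: 60000
sample_every: 1000
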