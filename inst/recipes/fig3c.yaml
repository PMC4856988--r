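name: fig3c
description: >
  Eu-/heterochromatin blocks: 300 light-green beads alternate with 100 pink
  beads along the fiber; red factors bind pink and green factors bind
  light-green.  Large and small pyramids alternate in the contact map.
units: {sigma_nm: 30, kbp_per_bead: 3}
box_edge_nm: 3000
fibers:
  - {n_beads: 5000, pattern: blocks, blocks: {light_green: 300, pink: 100}}
factors:
  - {color: red, count: 250, affinity: {pink: 8.0}, activation_time: 10000}
  - {color: green, count: 250, affinity: {light_green: 8.0}, activation_time: 10000}
duration: 60000
sample_every: 1000
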