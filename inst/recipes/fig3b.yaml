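name: fig3b
description: >
  Gene deserts: blocks of 400 binding beads (blue, with one bead in 20
  pink) alternate with 100-bead non-binding gray deserts; red factors bind
  pink strongly and blue weakly.  Domain boundaries fall inside the gray
  segments.
units: {sigma_nm: 30, kbp_per_bead: 3}
box_edge_nm: 3000
fibers:
  - {n_beads: 5000, pattern: deserts, block_size: 400, desert_size: 100,
     every: 20, color: pink, base_color: blue, desert_color: gray}
factors:
  - color: red
    count: 250
    affinity: {pink: 8.0, blue: 3.0}
    activation_time: 10000
duration: 60000
sample_every: 1000
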