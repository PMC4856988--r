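name: fig2a
description: >
  Two-species toy model: one bead in 20 is a binding bead, alternating pink
  and light-green along the fiber; 250 red and 250 green factors bind their
  cognate color strongly and other beads weakly.
units: {sigma_nm: 30, kbp_per_bead: 3}
box_edge_nm: 3000
fibers:
  - {n_beads: 5000, pattern: alternating, every: 20,
     alternating_colors: [pink, light_green], base_color: blue}
factors:
  - {color: red, count: 250, affinity: {pink: 8.0, blue: 3.0},
     activation_time: 10000}
  - {color: green, count: 250, affinity: {light_green: 8.0, blue: 3.0},
     activation_time: 10000}
duration: 60000
sample_every: 1000
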