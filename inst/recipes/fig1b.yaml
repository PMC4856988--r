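name: fig1b
description: >
  As fig1a but pink beads randomly distributed with the same mean linear
  density (1 in 20), so gaps are exponential ("Poisson clumping").
units: {sigma_nm: 30, kbp_per_bead: 3}
box_edge_nm: 3000
fibers:
  - {n_beads: 5000, pattern: poisson, rate: 0.05, color: pink, base_color: blue}
factors:
  - color: red
    count: 250
    affinity: {pink: 8.0, blue: 3.0}
    activation_time: 10000
duration: 60000
sample_every: 1000
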