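name: fig2c
description: >
  Five-species system: red, green, dark-blue, purple and black factors (500
  each) bind at 7.1 kBT to five sets of cognate sites scattered randomly
  (one site per color per 20 beads on average) along 20 identical fibers of
  2000 beads (6 Mbp) each.
units: {sigma_nm: 30, kbp_per_bead: 3}
box_edge_nm: 6000
fibers:
  - {n_beads: 2000, replicates: 20, pattern: scatter, rate: 0.05,
     scatter_colors: [site_red, site_green, site_darkblue, site_purple, site_black],
     base_color: blue}
factors:
  - {color: red, count: 500, affinity: {site_red: 7.1}, activation_time: 10000}
  - {color: green, count: 500, affinity: {site_green: 7.1}, activation_time: 10000}
  - {color: darkblue, count: 500, affinity: {site_darkblue: 7.1}, activation_time: 10000}
  - {color: purple, count: 500, affinity: {site_purple: 7.1}, activation_time: 10000}
  - {color: black, count: 500, affinity: {site_black: 7.1}, activation_time: 10000}
duration: 60000
sample_every: 1000
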