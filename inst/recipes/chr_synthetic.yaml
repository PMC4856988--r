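name: chr_synthetic
description: >
  Chromosome-style run on a synthetic annotation with chr12-like
  statistics: 15 Mbp at 1 kbp/bead (20.8-nm beads), ~4% pink
  (states 1/4/5), ~5.9% light-green (states 9/10), ~71% gray (low GC,
  threshold calibrated to the state-13 fraction); 300 red factors bind
  pink strongly / light-green weakly, 3000 black proteins bind gray.
units: {sigma_nm: 20.8, kbp_per_bead: 1}
box_edge_nm: 8900
fibers:
  - pattern: annotation
    region_bp: 15000000
    bead_bp: 1000
    proportions: {active: 0.04, elongation: 0.0587, heterochromatin: 0.71}
factors:
  - {color: red, count: 300, affinity: {pink: 8.0, light_green: 3.0},
     activation_time: 10000}
  - {color: black, count: 3000, affinity: {gray: 8.0},
     activation_time: 10000}
duration: 60000
sample_every: 1000
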