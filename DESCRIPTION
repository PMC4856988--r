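Package: chromobridge
Title: Coarse-Grained Chromatin Polymer Simulations with Bridging-Induced
    Clustering of Chromatin-Binding Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fitting-free polymer model of interphase chromosomes in which
    diffusing multivalent protein spheres ("transcription factors") bind
    cognate beads on a bead-and-spring chromatin fiber and spontaneously
    cluster through the bridging-induced attraction.  Provides an overdamped
    Brownian-dynamics engine (FENE bonds, Kratky-Porod bending, truncated and
    shifted Lennard-Jones binding, periodic box), a genome-annotation painter
    that converts chromatin-state intervals and GC content into per-bead
    colors (with a synthetic-annotation generator), and the full analysis
    layer: Hi-C-like contact maps, contact-probability scaling exponents,
    cluster statistics and color purity, rosettograms, the disorganized
    fraction, and topological-domain boundary detection via Janus/difference
    and insulation signals with boundary-concordance scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    IRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
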