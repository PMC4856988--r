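---
title: "Modeling chromosome folding through bridging-induced clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chromosome folding through bridging-induced clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromobridge)
```

## The model

`chromobridge` implements a fitting-free coarse-grained model of interphase
chromosome organization.  A chromatin fiber is a bead-and-spring polymer;
diffusing spheres ("transcription factors", or heterochromatin proteins)
bind cognate beads transiently.  Because a sphere can touch two or more
beads at once, binding creates molecular bridges that stabilize loops, and
bound factors spontaneously cluster — the *bridging-induced attraction* —
even though no factor–factor or bead–bead attraction is ever specified.
Clustering in turn folds the fiber into rosettes and topological domains
whose contact maps resemble Hi-C data.

### Interactions

* **Backbone and permanent loops**: FENE springs,
  $U(r) = -\tfrac{1}{2} K R_0^2 \log\left(1 - r^2/R_0^2\right)$ with
  $K = 30\,k_BT/\sigma^2$ and maximum extension $R_0 = 1.6\,\sigma$
  (the Kremer–Grest convention), combined with WCA sterics between the
  bonded beads.  $\sigma$ is the bead diameter.
* **Stiffness**: a Kratky–Porod bending term
  $U(\theta) = K_B (1 - \cos\theta)$ on consecutive bond vectors.  For a
  discrete chain the realized persistence length is
  $l_p = -1/\log(\coth K_B - 1/K_B)$ bead diameters; the familiar
  $l_p \simeq K_B$ holds only for stiff chains.  Fibers are specified by
  their persistence length (default $3\,\sigma$, i.e. 90 nm for 30-nm
  beads) and the engine inverts the exact relation, giving
  $K_B \approx 3.5\,k_BT$; with the naive first-order mapping the measured
  tangent-correlation decay would come out 16% short of the requested
  $l_p$.  Both mappings are exposed
  (`bend_stiffness_for_persistence(lp, exact = )`).
* **Sterics**: all non-cognate pairs (factor–factor, bead–bead, factor and
  non-cognate bead) interact only through the purely repulsive WCA
  potential ($\epsilon = 1\,k_BT$, cutoff $2^{1/6}\sigma$).
* **Binding**: a factor and a cognate bead interact through a
  Lennard-Jones potential truncated and shifted to zero at $1.8\,\sigma$
  (54 nm for 30-nm beads).  The affinity matrix (species color × bead
  color, in $k_BT$) is directional and sparse: absent entries mean pure
  sterics.  The nominal affinity $\epsilon$ is the LJ prefactor; because
  of the cutoff shift the realized well depth is $0.886\,\epsilon$, and
  run logs report both so the convention is auditable.  A bead carrying
  several colors (e.g. pink *and* gray) binds each corresponding species
  with its own strength; when a species can bind several of the bead's
  colors the strongest affinity applies.

### Units

Reduced units are $\sigma = k_BT = 1$, and one time unit is the Brownian
time $\tau = \sigma^2/D$ of a free sphere with the Stokes–Einstein
$D = k_BT/(3\pi\eta\sigma)$.  At the reference conditions (nucleoplasm
viscosity 10 cP, 300 K) this gives 0.6 ms for 30-nm (3-kbp) beads and
0.2 ms for 20.8-nm (1-kbp) beads; $\tau \propto \sigma^3$, so the two
mappings are mutually consistent.  Temperature enters only through this
conversion; 300 K reproduces the printed time mappings within rounding.
Bead sizes for other DNA contents follow
$d = 30\,(\mathrm{kbp}/3)^{1/3}$ nm (constant DNA volume density).

### Dynamics

The paper's reference implementation ran LAMMPS in its Brownian-dynamics
mode, which is underdamped Langevin dynamics with a stochastic thermostat.
We integrate the same dynamics with the BAOAB splitting (unit mass,
friction $\gamma$ proportional to particle diameter, $k_BT = 1$), at
`dt = 0.01` $\tau$.  Two numerical points motivated this choice over a
strictly overdamped first-order scheme:

* with overdamped Euler at $dt = 0.01\,\tau$ the random displacement per
  step is $\sqrt{2\,dt}\,\sigma \approx 0.14\,\sigma$ per axis — the same
  order as the gap between the FENE rest length and its hard maximum
  extension — and the combined FENE+WCA stiffness
  ($\sim 900\,k_BT/\sigma^2$ at the bond minimum) violates the explicit
  stability bound unless $dt \lesssim 2\times10^{-3}\,\tau$;
* with inertia the per-step move is $v\,dt \approx 0.02\,\sigma$, the bond
  oscillation is resolved ($\omega\,dt \approx 0.3$), and on times beyond
  $m/\gamma = 1\,\tau$ the motion is diffusive with exactly
  $D = k_BT/\gamma$, so the unit mapping above is unchanged.

Free-particle mean-squared displacement is $6Dt$ at long times (the test
suite checks 5% agreement at $t = 100\,\tau$).  Non-bonded interactions
use a Verlet pair list (0.4 $\sigma$ skin) over a linked-cell grid with
minimum-image periodic distances; the list is rebuilt whenever any
particle has moved half a skin.  Bonds beyond $R_0$ or non-finite
coordinates abort the run with the offending bond and step, rather than
silently continuing.

Zero-temperature operations (overlap removal after initial placement, and
the relaxation checks in the tests) use displacement-capped steepest
descent (`relax_state()`), which is monotone in energy by construction.

Two further numerical points.  The discrete bending force contains a
factor of one over the bond length, so chains must keep a steric core on
bonded pairs; the engine's `phantom = TRUE` mode therefore switches off
*non-bonded* interactions only (an ideal, non-self-avoiding chain with
intact bonds), which is the configuration used to validate the realized
persistence length — with full excluded volume the measured l_p of a
nominal 3-sigma chain swells to ~3.5 sigma, a real feature of
self-avoiding chains rather than an integration artifact.  And the
stated interaction cutoffs are exact: pair energies are identically zero
at and beyond 1.8 sigma (binding) and 2^(1/6) sigma (sterics), with the
shift constants precomputed once per run.

### Protocol

A run starts from a self-avoiding random walk (grown with unit bonds,
rejecting placements closer than $0.8\,\sigma$, then briefly relaxed) with
factors dispersed uniformly.  All affinities are off until each species'
activation time (default $10^4\,\tau$), so the fiber equilibrates as a
plain excluded-volume chain first; binding then switches on, and optional
scheduled affinity changes (e.g. a second species acquiring a stronger
affinity mid-run) are applied at their set times.  Snapshots are taken
every $10^3\,\tau$ by default.  Every source of randomness derives from
one master seed, and a run is bit-reproducible on one platform given the
seed.

## Analyses

* **Clusters** (`find_clusters`): single-linkage connected components
  under a strict 90-nm center-distance cutoff, over a configurable
  participant set (factors, bound factors, binding beads, one species...).
  Clusters are groups of ≥ 2; singletons count only in fractions.
  `cluster_timeseries` reports mean cluster size and clustered fraction
  per snapshot; steady-state values average the final 20% of snapshots.
* **Purity** (`cluster_purity`): fraction of a cluster's members carrying
  its dominant color; summarized as the fraction of pure clusters and the
  fraction with purity above 0.8.
* **Rosettograms** (`rosettogram`): one row per cluster, one column per
  high-affinity bead in fiber order; runs of abutting pixels are rosette
  petals at consecutive binding sites.  In multi-species systems a pixel
  takes the species color of the nearest bound factor (ties to the lower
  species index).
* **Disorganized fraction** (`disorganized_fraction`): the fraction of
  high-affinity beads that do *not* share a cluster with either of their
  nearest high-affinity neighbors along the fiber.  The complement is the
  neighbor-sharing fraction, so the two sum to one exactly; unclustered
  beads count as disorganized.
* **Contact maps** (`contact_map`): a contact is scored when two bead
  centers lie within 150 nm (inclusive); counts are binned over 40
  adjacent beads and aggregated over snapshots.  The high-resolution
  variant (no binning, 90 nm) reproduces the zoomed views.  Each bead
  scores a self-contact so the unnormalized diagonal is maximal.
* **Contact probability** (`contact_probability`, `fit_scaling`):
  $P(s)$ is the contact frequency at bead separation $s$ within a fiber;
  exponents come from least squares on $\log P$ vs $\log s$.  Patterned
  fibers show two regimes split at the domain scale — roughly $s^{-0.6}$
  to $s^{-1}$ within domains and near $s^{-2}$ between them; an ideal
  random walk gives the classic $-3/2$.  The split point is exposed
  because the "domain scale" of a mixed pattern is set by its largest
  block.  On periodically patterned fibers the inter-domain fit should
  stop at one pattern period: beyond it equivalent blocks re-align and
  bridging clusters put bumps in $P(s)$, so the package fits the
  cross-block regime between half the largest block and one period
  (e.g. $s \in [150, 400]$ for the 300/100 block pattern).
* **Boundaries** (`janus_profiles`, `find_boundaries`): per bin, contacts
  within a window to the left and right; the difference (right − left)
  crosses zero upward at a domain boundary, and peaks of its derivative
  (the insulation signal) sharpen the call.  The difference signal is
  smoothed with a 5-bin moving average before detection; the window
  defaults to 10 bins (≈ 400 beads at standard binning, the domain scale
  of the patterned fibers).  Weak crossings below 20% of the strongest
  score are discarded.  `boundary_concordance` scores two boundary lists
  by greedy nearest-first one-to-one matching within a tolerance
  (100 kbp at genome scale) and reports the recovered fraction of the
  reference set plus a permutation null with the same boundary count.
  Automated detection is expected to land near the source method's
  automated figure rather than its visually fine-tuned one, since no
  manual adjustment is applied.

## Genome painting

`paint_beads` maps ChromHMM-style state intervals (BED, both the
`1_Active_Promoter` and plain-integer name dialects) and windowed GC
content onto bead colors at 1 or 3 kbp per bead: ≥ 90 bp of states 1/4/5
makes a bead pink (strong factor binding), ≥ 90 bp of states 9/10 makes it
light-green (weak binding), GC strictly below the threshold makes it gray
(heterochromatin-protein binding; without a GC track, ≥ 90 bp of state 13
is used), all else is blue.  The rules act independently, so beads can
carry several colors.  Because the wording "a region of 90 bp or more"
does not say whether qualifying states are pooled, both readings are
implemented; the default pools the total qualifying overlap within the
bead, which is invariant to interval fragmentation.  Beads at exactly the
GC threshold are not gray (strict inequality), N runs are excluded from
the GC denominator, and mostly-N beads are painted blue and logged.
`calibrate_gc_threshold` returns the GC quantile whose below-threshold
fraction equals the state-13 bead fraction, which is how the 41.8% / 48.4%
thresholds of the source maps were chosen.  Uncovered beads raise a gap
error rather than silently painting blue.

`synthesize_annotation` generates a gap-free synthetic state partition
plus an autocorrelated GC profile realizing requested per-bead eligible
fractions (qualifying intervals of ≥ 90 bp are placed inside disjoint
thirds of each selected bead, so the painted fractions match the request
to rounding).  It emulates the marginal statistics real tracks feed into
the painter — eligible-bead fractions, interval fragmentation, GC–state
correlation — but not the long-range domain structure of real chromatin
annotation, so passing pipeline tests on synthetic tracks validates the
painting logic, not biological realism of any particular genome.

## Recipes and study conditions

Shipped YAML recipes (`load_recipe`) encode the standard setups: `fig1a`
(5000-bead fiber, pink every 20th bead, 250 factors in a 3-µm box — 15 nM
factors, 0.26% chromatin volume fraction), `fig1b` (random pink sites at
the same density), `fig2a` (alternating pink/light-green sites with red
and green factors), `fig2c` (five species × 500 factors on 20 fibers of
2000 beads at 7.1 kBT), `fig3a`–`fig3d` (homogeneous control, gene
deserts, eu/heterochromatin blocks, permanent 324-bead loops) and
`chr_synthetic` (a 15-Mbp, 1-kbp-per-bead chromosome-style run painted
from a synthetic annotation, 300 factors + 3000 heterochromatin
proteins).  `scale_recipe` shrinks bead and factor counts together and
rescales the box to preserve every volume fraction, so scaled-down runs
keep the full-scale concentrations and local physics.

Where the source material prints no affinity values ("strength
indicated"), the defaults were fixed once by calibrating the single-color
toy model against its two reported steady-state observables — cluster
size (≈ 12 factors) and the disorganized fraction (f_d ≈ 0.2) — over a
scan of affinity pairs on scaled-down systems: **strong (cognate) binding
8 kBT, weak (non-specific) binding 3 kBT**.  The scan showed the two
observables pull in opposite directions along the weak-binding axis:
above ~4 kBT the non-specific attraction compacts the fiber globally and
clusters recruit binding sites from anywhere along the chain (large
clusters, but f_d ≈ 0.5), while at 2 kBT folding is strictly local
(f_d ≈ 0.1) with smaller arrested clusters; 8/3 kBT reproduces the
rosette-like local organization at the largest compatible cluster size.
Cluster sizes at desk scale are additionally quantized (N factors in k
clusters) and arrested coarsening makes the cluster count
seed-dependent, so size checks average several seeds.  These affinities
are config fields in every recipe, never constants in the analysis code.

## Problem sizes used by the tests

The packaged test-suite exercises the full pipeline on scaled-down
systems chosen as the package's own test conditions: the single- and
two-species clustering studies run at 2/25 of the toy-model size (400
beads, 20 factors — same concentrations, same local physics) for
1.2–1.6 × 10^4 time units with a shortened pre-binding equilibration
(10^3 instead of 10^4 time units: the pre-binding phase only
decorrelates the self-avoiding walk, and binding statistics are local);
the five-color system runs at 1/40 size and the block-patterned fiber at
1/5 size.  Cluster-size checks for the single-species system average
5 seeds.  Full-scale runs use exactly the same code paths via
`run_recipe(..., scale = 1)`.

## What desk-scale runs do and do not show

Scaled-down runs preserve all concentrations and the local binding
physics, and they reproduce the qualitative phenomenology end to end:
factors cluster only when multivalent (the monovalent control stays
unclustered), clusters are color-pure far beyond a color-shuffling null,
rosette-like local organization gives the reported neighbor-sharing
fraction (~0.8), block-patterned fibers form domains with the expected
intra-domain contact-decay exponent, and boundary detection localizes
block junctions.  Two absolute numbers do *not* transfer to desk scale:
steady-state cluster sizes are quantized (N factors shared among k
clusters) and arrest at ~8–9 factors per cluster in the single-color
system (the full-size value of ~12 needs hundreds of factors and the
full 5 × 10^4-unit protocol), and the two-species alternating system
over-merges (per-cluster counts of ~17–20 instead of ~8) because only a
couple of clusters per species fit in the scaled box.  These are
finite-size effects of the test conditions, not model changes; the
full-scale recipes run the identical code.

## Known limitations

* No hydrodynamic interactions, twist/supercoiling energetics or
  linking-number conservation; the permanent-loop recipe treats loops as
  torsionally relaxed.
* Factor counts are fixed (no exchange with a reservoir), and "affinity"
  means the LJ epsilon, not a measured dissociation constant.
* Boundary detection is fully automated; no visual fine-tuning is
  applied, which systematically lowers concordance scores relative to
  curated boundary sets.
* The synthetic annotation matches marginal statistics of real tracks,
  not their long-range structure; conclusions about real chromosomes
  require real annotation input.
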