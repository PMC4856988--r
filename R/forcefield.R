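#' Force-field parameters
#'
#' Collects the interaction parameters of the bead-spring chromatin model.
#' Backbone (and permanent-loop) bonds are FENE springs with maximum extension
#' `fene_r0` (1.6 sigma) combined with WCA sterics between the bonded beads;
#' fiber stiffness comes from a Kratky-Porod bending term
#' U = kb (1 - cos theta); all non-cognate pairs interact through the purely
#' repulsive WCA potential; a factor and a cognate chromatin bead interact
#' through a Lennard-Jones potential truncated and shifted to zero at
#' `attraction_cutoff` (1.8 sigma, i.e. 54 nm for 30-nm beads), whose epsilon
#' is taken from the affinity matrix.
#'
#' The affinity matrix is directional: rows are factor-species colors, columns
#' are bead colors, entries in kBT.  A missing entry (or zero) means pure
#' sterics, identical to non-cognate pairs.
#'
#' @param fene_k FENE spring constant, kBT/sigma^2.
#' @param fene_r0 FENE maximum extension, sigma.
#' @param bend_kb default bending modulus, kBT (fibers usually override it
#'   through their persistence length, see [bend_stiffness_for_persistence()]).
#' @param eps_steric WCA well parameter for non-cognate pairs, kBT.
#' @param attraction_cutoff cutoff of the cognate attraction, sigma.
#' @param affinity numeric matrix with rownames = species colors and
#'   colnames = bead colors, in kBT; or `NULL` for a sterics-only system.
#' @param palette character vector of valid color labels; defaults to the
#'   union of the affinity dimnames and the non-binding color `"blue"`.
#' @return an object of class `force_field`.
#' @export
force_field <- function(fene_k = 30, fene_r0 = 1.6, bend_kb = 3,
                        eps_steric = 1, attraction_cutoff = 1.8,
                        affinity = NULL, palette = NULL) {
  stopifnot(fene_k > 0, fene_r0 > 1, bend_kb >= 0, eps_steric > 0,
            attraction_cutoff > 1)
  if (!is.null(affinity)) {
    stopifnot(is.matrix(affinity), !is.null(rownames(affinity)),
              !is.null(colnames(affinity)), all(affinity >= 0))
  }
  if (is.null(palette)) {
    palette <- unique(c(rownames(affinity), colnames(affinity), "blue"))
  }
  structure(list(fene_k = fene_k, fene_r0 = fene_r0, bend_kb = bend_kb,
                 eps_steric = eps_steric,
                 attraction_cutoff = attraction_cutoff,
                 affinity = affinity, palette = palette),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("force field: FENE k=%.3g R0=%.3g | WCA eps=%.3g | cutoff %.3g sigma\n",
              x$fene_k, x$fene_r0, x$eps_steric, x$attraction_cutoff))
  if (!is.null(x$affinity)) {
    cat("affinities (kBT), realized well depth in brackets:\n")
    for (sp in rownames(x$affinity)) for (bc in colnames(x$affinity)) {
      eps <- x$affinity[sp, bc]
      if (eps > 0)
        cat(sprintf("  %s -> %s : %.3g (%.3g)\n", sp, bc, eps,
                    -lj_shifted_energy(2^(1 / 6), eps, x$attraction_cutoff)))
    }
  }
  invisible(x)
}

#' FENE bond energy
#'
#' U(r) = -k R0^2 / 2 * log(1 - (r/R0)^2): finite for r < R0, divergent at the
#' maximum extension R0.  A bond at or beyond R0 is an integration failure and
#' raises an error identifying the bond.
#'
#' @param r bond length(s), sigma.
#' @param ff a [force_field()] (only `fene_k` and `fene_r0` are used).
#' @param bond_id,step optional context used in the overstretch diagnostic.
#' @return energy in kBT.
#' @export
fene_energy <- function(r, ff = force_field(), bond_id = NA, step = NA) {
  if (any(r < 0)) stop("negative bond length")
  bad <- r >= ff$fene_r0
  if (any(bad)) {
    stop(sprintf(
      "exploded bond: length %.4g sigma >= maximum extension %.4g sigma (bond %s, step %s)",
      max(r), ff$fene_r0, paste(bond_id, collapse = ","), as.character(step)))
  }
  -0.5 * ff$fene_k * ff$fene_r0^2 * log(1 - (r / ff$fene_r0)^2)
}

#' FENE bond force magnitude, dU/dr (positive = restoring pull)
#' @inheritParams fene_energy
#' @return dU/dr in kBT/sigma.
#' @export
fene_force <- function(r, ff = force_field()) {
  if (any(r >= ff$fene_r0)) stop("bond length at or beyond maximum extension")
  ff$fene_k * r / (1 - (r / ff$fene_r0)^2)
}

#' Kratky-Porod bending energy
#'
#' U(theta) = kb (1 - cos theta), with theta the angle between consecutive
#' bond vectors (theta = 0 for a straight chain, the energy minimum).
#' Cosines are clamped to \[-1, 1\] against rounding.
#'
#' @param theta angle(s) in radians, in \[0, pi\].
#' @param kb bending modulus in kBT.
#' @return energy in kBT.
#' @export
bend_energy <- function(theta, kb = 3) {
  kb * (1 - pmin(1, pmax(-1, cos(theta))))
}

#' Map bending stiffness to persistence length and back
#'
#' For the discrete Kratky-Porod chain the tangent-tangent correlation decays
#' per joint by the Langevin function L(kb) = coth(kb) - 1/kb, so the realized
#' persistence length (in bead diameters) is lp = -1 / log L(kb).  The common
#' first-order approximation lp ~= kb sigma / kBT is accurate only for stiff
#' chains; at lp = 3 sigma the exact inversion gives kb ~= 3.5 kBT.  The
#' engine uses the exact relation so that a requested persistence length is
#' the one actually measured from tangent correlations.
#'
#' @param kb bending modulus, kBT.
#' @param lp persistence length, sigma.
#' @param exact use the exact discrete-chain relation (default) or the
#'   first-order lp = kb approximation.
#' @return `persistence_from_bend_stiffness`: lp in sigma;
#'   `bend_stiffness_for_persistence`: kb in kBT.
#' @export
persistence_from_bend_stiffness <- function(kb, exact = TRUE) {
  if (!exact) return(kb)
  L <- 1 / tanh(kb) - 1 / kb
  -1 / log(L)
}

#' @rdname persistence_from_bend_stiffness
#' @export
bend_stiffness_for_persistence <- function(lp, exact = TRUE) {
  stopifnot(lp > 0)
  if (!exact) return(lp)
  target <- exp(-1 / lp)
  f <- function(kb) (1 / tanh(kb) - 1 / kb) - target
  stats::uniroot(f, c(1e-6, 1e4), tol = 1e-12)$root
}

# Unshifted LJ (sig = particle contact diameter)
lj_energy <- function(r, eps, sig = 1) {
  sr6 <- (sig / r)^6
  4 * eps * (sr6^2 - sr6)
}

# LJ truncated and shifted to zero at rc; 0 beyond rc.
lj_shifted_energy <- function(r, eps, rc, sig = 1) {
  shift <- lj_energy(rc, eps, sig)
  ifelse(r < rc, lj_energy(r, eps, sig) - shift, 0)
}

lj_force <- function(r, eps, sig = 1) {   # dU/dr
  sr6 <- (sig / r)^6
  -24 * eps * (2 * sr6^2 - sr6) / r
}

# WCA: LJ truncated and shifted at its minimum 2^(1/6) sig -> purely repulsive
wca_energy <- function(r, eps = 1, sig = 1) {
  rc <- 2^(1 / 6) * sig
  ifelse(r < rc, lj_energy(r, eps, sig) + eps, 0)
}

wca_force <- function(r, eps = 1, sig = 1) {
  rc <- 2^(1 / 6) * sig
  ifelse(r < rc, lj_force(r, eps, sig), 0)
}

resolve_affinity <- function(ff, species_color, bead_colors) {
  if (!all(c(species_color, bead_colors) %in% ff$palette)) {
    bad <- setdiff(c(species_color, bead_colors), ff$palette)
    stop("unknown color(s): ", paste(bad, collapse = ", "),
         " (configured palette: ", paste(ff$palette, collapse = ", "), ")")
  }
  if (is.null(ff$affinity) || !(species_color %in% rownames(ff$affinity)))
    return(0)
  hits <- intersect(bead_colors, colnames(ff$affinity))
  if (!length(hits)) return(0)
  max(ff$affinity[species_color, hits])
}

#' Non-bonded pair energy between a factor and a chromatin bead
#'
#' Cognate pairs (positive affinity-matrix entry) interact through the
#' truncated and shifted Lennard-Jones potential, continuous and identically
#' zero at and beyond `attraction_cutoff`; all other pairs are purely
#' repulsive WCA.  A bead carrying several colors uses the strongest affinity
#' the species has for any of them.
#'
#' @param r center-center distance(s), sigma.
#' @param species_color factor species color label.
#' @param bead_color bead color label, possibly a set (character vector).
#' @param ff a [force_field()] carrying the affinity matrix.
#' @param sig contact diameter of the pair, sigma (mean of the two diameters).
#' @return energy in kBT.
#' @export
pair_energy <- function(r, species_color, bead_color, ff = force_field(),
                        sig = 1) {
  stopifnot(all(r > 0))
  eps <- resolve_affinity(ff, species_color, bead_color)
  if (eps > 0) {
    lj_shifted_energy(r, eps, ff$attraction_cutoff * sig, sig)
  } else {
    wca_energy(r, ff$eps_steric, sig)
  }
}

#' @rdname pair_energy
#' @return `pair_force`: dU/dr in kBT/sigma.
#' @export
pair_force <- function(r, species_color, bead_color, ff = force_field(),
                       sig = 1) {
  stopifnot(all(r > 0))
  eps <- resolve_affinity(ff, species_color, bead_color)
  if (eps > 0) {
    ifelse(r < ff$attraction_cutoff * sig, lj_force(r, eps, sig), 0)
  } else {
    wca_force(r, ff$eps_steric, sig)
  }
}
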