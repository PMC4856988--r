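#' Factor (binding-protein) species
#'
#' A species of diffusing spheres that bind cognate chromatin beads.  The
#' affinity row gives, per bead color, the epsilon (kBT) of the truncated and
#' shifted Lennard-Jones attraction; colors absent from the row are purely
#' steric.  Affinities are switched on at `activation_time` (the system
#' equilibrates with sterics only before that).  `valence = 1` caps a factor
#' at a single simultaneous cognate contact (the monovalent control:
#' attraction only toward its nearest cognate bead in range); the default
#' `Inf` leaves valence emergent.
#'
#' @param color species label (must differ from other species).
#' @param count number of spheres.
#' @param affinity named numeric vector, bead color -> kBT.
#' @param diameter sphere diameter in bead diameters (sigma).
#' @param activation_time simulation time at which binding switches on.
#' @param valence `Inf` (multivalent, emergent) or `1` (monovalent control).
#' @return an object of class `factor_species`.
#' @export
factor_species <- function(color, count, affinity,
                           diameter = 1, activation_time = 1e4,
                           valence = Inf) {
  stopifnot(count >= 0, diameter > 0, activation_time >= 0,
            valence %in% c(1, Inf))
  stopifnot(is.numeric(affinity), !is.null(names(affinity)),
            all(affinity >= 0))
  structure(list(color = color, count = as.integer(count),
                 affinity = affinity, diameter = diameter,
                 activation_time = activation_time, valence = valence),
            class = "factor_species")
}

#' Assemble fibers and factor species into a simulation system
#'
#' Builds the particle table (beads of all fibers first, then factors by
#' species), the bonded topology (backbone + permanent loops), the bending
#' terms (stiffness from each fiber's persistence length), the color palette
#' and the species-by-color affinity matrix.
#'
#' @param fibers a [fiber_spec()] or list of them.
#' @param factors a [factor_species()] or list of them (may be empty).
#' @param box_edge cubic box edge, sigma.
#' @param ff a [force_field()] providing the scalar interaction parameters
#'   (its affinity matrix, if any, is replaced by the one assembled from the
#'   species).
#' @param units a [unit_system()] used by analyses to convert nm thresholds.
#' @return an object of class `bead_system`.
#' @export
bead_system <- function(fibers, factors = list(), box_edge,
                        ff = force_field(), units = unit_system()) {
  if (inherits(fibers, "fiber_spec")) fibers <- list(fibers)
  if (inherits(factors, "factor_species")) factors <- list(factors)
  stopifnot(length(fibers) >= 1 || length(factors) >= 1, box_edge > 0)
  sp_colors <- vapply(factors, `[[`, character(1), "color")
  if (anyDuplicated(sp_colors)) stop("factor species colors must be unique")

  bead_colors <- unlist(lapply(fibers, function(f) unlist(f$colors)))
  aff_colors <- unlist(lapply(factors, function(fs) names(fs$affinity)))
  palette <- unique(c(sort(unique(bead_colors)), sp_colors, aff_colors, "blue"))
  if (length(palette) > 31) stop("at most 31 distinct colors supported")

  n_beads <- sum(vapply(fibers, `[[`, integer(1), "n_beads"))
  n_fact <- sum(vapply(factors, `[[`, integer(1), "count"))
  n <- n_beads + n_fact

  fiber_id <- integer(0); idx_in_fiber <- integer(0)
  colorbits <- integer(0); bonds <- NULL; angles <- NULL; angle_kb <- numeric(0)
  off <- 0L
  for (fi in seq_along(fibers)) {
    f <- fibers[[fi]]
    fiber_id <- c(fiber_id, rep(fi, f$n_beads))
    idx_in_fiber <- c(idx_in_fiber, seq_len(f$n_beads) - 1L)
    colorbits <- c(colorbits, vapply(f$colors, function(cs) {
      sum(bitwShiftL(1L, match(cs, palette) - 1L))
    }, integer(1)))
    bb <- cbind(off + seq_len(f$n_beads - 1L), off + seq_len(f$n_beads - 1L) + 1L)
    if (!is.null(f$loops)) {
      lp <- f$loops + off
      bb <- rbind(bb, lp)
    }
    bonds <- rbind(bonds, bb)
    if (f$n_beads >= 3) {
      aa <- cbind(off + seq_len(f$n_beads - 2L),
                  off + seq_len(f$n_beads - 2L) + 1L,
                  off + seq_len(f$n_beads - 2L) + 2L)
      angles <- rbind(angles, aa)
      kb <- bend_stiffness_for_persistence(f$persistence_length)
      angle_kb <- c(angle_kb, rep(kb, nrow(aa)))
    }
    off <- off + f$n_beads
  }

  species <- c(rep(0L, n_beads),
               unlist(lapply(seq_along(factors), function(si)
                 rep(si, factors[[si]]$count))))
  diam <- c(rep(1, n_beads),
            unlist(lapply(factors, function(fs) rep(fs$diameter, fs$count))))
  if (!length(species)) species <- integer(0)

  S <- length(factors)
  eps <- matrix(0, nrow = S, ncol = length(palette),
                dimnames = list(sp_colors, palette))
  for (si in seq_len(S)) {
    aff <- factors[[si]]$affinity
    unknown <- setdiff(names(aff), palette)
    if (length(unknown))
      stop("species '", sp_colors[si], "' has affinity for unknown color(s): ",
           paste(unknown, collapse = ", "))
    eps[si, names(aff)] <- aff
  }
  ff$affinity <- eps
  ff$palette <- palette

  structure(list(fibers = fibers, factors = factors, box_edge = box_edge,
                 ff = ff, units = units, palette = palette,
                 n_beads = as.integer(n_beads), n_factors = as.integer(n_fact),
                 n_particles = as.integer(n),
                 species = species, diam = diam, colorbits = colorbits,
                 fiber_id = fiber_id, idx_in_fiber = idx_in_fiber,
                 bonds = if (is.null(bonds)) matrix(0L, 0, 2) else bonds,
                 angles = if (is.null(angles)) matrix(0L, 0, 3) else angles,
                 angle_kb = angle_kb),
            class = "bead_system")
}

#' @export
print.bead_system <- function(x, ...) {
  cat(sprintf("bead system: %d bead(s) in %d fiber(s), %d factor(s), box %.4g sigma\n",
              x$n_beads, length(x$fibers), x$n_factors, x$box_edge))
  comp <- box_composition(x$n_beads, x$units$sigma_nm,
                          x$box_edge * x$units$sigma_nm)
  cat(sprintf("  chromatin volume fraction %.3g%%\n", comp$volume_fraction_pct))
  for (fs in x$factors) {
    fc <- box_composition(fs$count, fs$diameter * x$units$sigma_nm,
                          x$box_edge * x$units$sigma_nm)
    cat(sprintf("  %s factors: n=%d, %.3g nM, activation t=%.3g, affinities: %s\n",
                fs$color, fs$count, fc$concentration_nM, fs$activation_time,
                paste(sprintf("%s=%.3g", names(fs$affinity), fs$affinity),
                      collapse = " ")))
  }
  invisible(x)
}

#' Per-bead binding flag
#'
#' A bead is a binding bead for a species when the species has positive
#' affinity for one of the bead's colors; with `species = NULL`, for any
#' species.  High-affinity beads (`high_only = TRUE`) are those at the
#' species' maximum affinity entry.
#'
#' @param system a [bead_system()].
#' @param species species color label or `NULL` for any.
#' @param high_only restrict to the species' strongest-bound color(s).
#' @return logical vector over beads (length `system$n_beads`).
#' @export
binding_beads <- function(system, species = NULL, high_only = FALSE) {
  eps <- system$ff$affinity
  rows <- if (is.null(species)) seq_len(nrow(eps)) else match(species, rownames(eps))
  if (anyNA(rows)) stop("unknown species: ", species)
  hit <- rep(FALSE, system$n_beads)
  for (r in rows) {
    row <- eps[r, ]
    cols <- if (high_only) names(row)[row == max(row) & row > 0]
            else names(row)[row > 0]
    if (!length(cols)) next
    mask <- sum(bitwShiftL(1L, match(cols, system$palette) - 1L))
    hit <- hit | bitwAnd(system$colorbits[seq_len(system$n_beads)], mask) > 0L
  }
  hit
}
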