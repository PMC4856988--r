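#' Reduced simulation units and their physical mapping
#'
#' A `unit_system` fixes the correspondence between reduced simulation units
#' (bead diameter sigma, thermal energy kBT, Brownian time tau) and physical
#' units.  The chromatin fiber is coarse-grained so that one bead carries a
#' fixed amount of DNA (`kbp_per_bead`); the bead diameter follows from the
#' packing density of the 30-nm fiber (1 kbp per 10 nm of fiber, so a 3-kbp
#' bead is 30 nm across) and beads of different content conserve the volume
#' density of DNA.
#'
#' @param sigma_nm bead diameter in nm (reduced length unit sigma).
#' @param kbp_per_bead DNA content of one chromatin bead, in kbp.
#' @param viscosity_Pa_s nucleoplasm viscosity in Pa s (10 cP = 0.01 Pa s,
#'   ten-fold that of water).
#' @param temperature_K absolute temperature in K.
#' @return an object of class `unit_system`.
#' @examples
#' u <- unit_system()           # 30 nm / 3 kbp beads
#' physical_time_unit(u)        # ~0.6 ms per simulation time unit
#' @export
unit_system <- function(sigma_nm = 30, kbp_per_bead = 3,
                        viscosity_Pa_s = 0.01, temperature_K = 300) {
  stopifnot(sigma_nm > 0, kbp_per_bead > 0,
            viscosity_Pa_s > 0, temperature_K > 0)
  structure(list(sigma_nm = sigma_nm, kbp_per_bead = kbp_per_bead,
                 viscosity_Pa_s = viscosity_Pa_s,
                 temperature_K = temperature_K),
            class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf(
    "unit system: sigma = %.4g nm (%.3g kbp/bead), eta = %.3g Pa s, T = %.4g K\n",
    x$sigma_nm, x$kbp_per_bead, x$viscosity_Pa_s, x$temperature_K))
  cat(sprintf("  time unit tau = %.4g ms\n", physical_time_unit(x)))
  invisible(x)
}

.kB <- 1.380649e-23   # J/K
.NA_avogadro <- 6.02214076e23

#' Physical duration of one simulation time unit
#'
#' The reduced time unit is the Brownian time tau = sigma^2 / D of a sphere of
#' diameter sigma, with the Stokes-Einstein diffusion coefficient
#' D = kBT / (3 pi eta sigma).  tau therefore scales as sigma^3 at fixed
#' viscosity and temperature: 30-nm (3 kbp) beads give ~0.6 ms and 20.8-nm
#' (1 kbp) beads ~0.2 ms at 10 cP and 300 K.
#'
#' @param units a [unit_system()].
#' @return milliseconds per simulation time unit.
#' @export
physical_time_unit <- function(units = unit_system()) {
  sigma_m <- units$sigma_nm * 1e-9
  D <- .kB * units$temperature_K / (3 * pi * units$viscosity_Pa_s * sigma_m)
  tau_s <- sigma_m^2 / D
  tau_s * 1e3
}

#' Bead diameter for a given DNA content
#'
#' Beads of different genomic content keep the same volume density of DNA, so
#' the diameter scales as the cube root of the content:
#' d = 30 nm * (kbp / 3)^(1/3) with the 30-nm fiber reference packing of
#' 1 kbp per 10 nm (a 3-kbp bead is 30 nm).
#'
#' @param kbp DNA content per bead in kbp.
#' @param ref_nm,ref_kbp the reference bead (defaults 30 nm for 3 kbp).
#' @return diameter in nm.
#' @export
bead_diameter_for_content <- function(kbp, ref_nm = 30, ref_kbp = 3) {
  stopifnot(all(kbp > 0), ref_nm > 0, ref_kbp > 0)
  ref_nm * (kbp / ref_kbp)^(1 / 3)
}

#' Volume fraction and molar concentration of spheres in a periodic box
#'
#' @param n_particles number of spheres.
#' @param diameter_nm sphere diameter in nm.
#' @param box_edge_nm edge of the cubic box in nm.
#' @return a list with `volume_fraction_pct` (per cent of box volume occupied)
#'   and `concentration_nM`.
#' @examples
#' box_composition(250, 30, 3000)    # ~0.013% and ~15 nM (toy-model factors)
#' box_composition(5000, 30, 3000)   # ~0.26% chromatin, i.e. dilute
#' @export
box_composition <- function(n_particles, diameter_nm, box_edge_nm) {
  stopifnot(n_particles >= 0, diameter_nm > 0, box_edge_nm > 0)
  V_box_nm3 <- box_edge_nm^3
  vf <- n_particles * (pi / 6) * diameter_nm^3 / V_box_nm3 * 100
  V_box_L <- V_box_nm3 * 1e-24
  conc_nM <- n_particles / (.NA_avogadro * V_box_L) * 1e9
  list(volume_fraction_pct = vf, concentration_nM = conc_nM)
}
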