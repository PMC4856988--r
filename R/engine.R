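#' @useDynLib chromobridge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# assemble the C++ engine configuration from a system + positions
engine_config <- function(system, pos, vel = NULL, dt = 0.01, seed = 1,
                          n_steps = 0, sample_every_steps = 1,
                          schedule = NULL, phantom = FALSE) {
  S <- length(system$factors)
  act <- vapply(system$factors, function(fs)
    as.integer(min(ceiling(fs$activation_time / dt),
                   .Machine$integer.max - 1)), integer(1))
  mono <- vapply(system$factors, function(fs) fs$valence == 1, logical(1))
  if (is.null(schedule)) {
    sched <- list(step = integer(0), species = integer(0),
                  color = integer(0), eps = numeric(0))
  } else {
    stopifnot(all(c("time", "species", "bead_color", "eps") %in%
                    names(schedule)))
    if (any(schedule$time < 0)) stop("schedule with activation before time 0")
    si <- match(schedule$species, rownames(system$ff$affinity))
    ci <- match(schedule$bead_color, system$palette)
    if (anyNA(si) || anyNA(ci)) stop("schedule names unknown species/color")
    ord <- order(schedule$time)
    sched <- list(step = as.integer(ceiling(schedule$time[ord] / dt)),
                  species = si[ord], color = ci[ord] - 1L,
                  eps = schedule$eps[ord])
  }
  list(pos = pos, vel = vel, box = system$box_edge,
       bonds = system$bonds - 1L, angles = system$angles - 1L,
       angle_kb = system$angle_kb, diam = system$diam,
       species = system$species, colorbits = as.integer(system$colorbits),
       eps = unname(system$ff$affinity),
       activation_step = if (S) act else integer(0),
       monovalent = if (S) mono else logical(0),
       sched_step = sched$step, sched_species = sched$species,
       sched_color = sched$color, sched_eps = sched$eps,
       fene_k = system$ff$fene_k, fene_r0 = system$ff$fene_r0,
       rc_mult = system$ff$attraction_cutoff,
       eps_steric = system$ff$eps_steric,
       kT = 1, dt = dt, n_steps = n_steps,
       sample_every_steps = sample_every_steps, seed = seed,
       phantom = phantom)
}

#' Initial conformation: self-avoiding fibers plus dispersed factors
#'
#' Each fiber is grown as a self-avoiding random walk with unit bond length
#' (candidate beads within `min_dist` of any placed particle are rejected);
#' factors are then placed uniformly at random avoiding overlap, and a short
#' displacement-capped steepest-descent relaxation removes residual strain.
#' Deterministic under `seed`.
#'
#' @param system a [bead_system()].
#' @param seed integer seed.
#' @param min_dist minimum center distance during placement, sigma.
#' @param relax_steps steepest-descent steps after placement.
#' @param max_try placement retries before declaring the box over-dense.
#' @return a `bd_state`: list with `time`, `positions` (n x 3, wrapped into
#'   the box), `images` (periodic image counts), `velocities` (`NULL` until
#'   the first dynamics run), `box_edge`.
#' @export
initialize_conformation <- function(system, seed = 1, min_dist = 0.8,
                                    relax_steps = 200, max_try = 5000L) {
  lens <- vapply(system$fibers, `[[`, integer(1), "n_beads")
  pos <- if (length(lens) && sum(lens) > 0)
    cpp_grow_saw(lens, system$box_edge, min_dist, max_try, seed)
  else matrix(0, 0, 3)
  if (system$n_factors > 0) {
    fpos <- cpp_place_spheres(system$n_factors, pos, system$box_edge,
                              min_dist, max_try, seed + 1)
    pos <- rbind(pos, fpos)
  }
  if (relax_steps > 0) {
    cfg <- engine_config(system, pos)
    # binding off during relaxation: sterics + bonds only
    cfg$activation_step <- rep(.Machine$integer.max,
                               length(cfg$activation_step))
    res <- cpp_relax(cfg, as.integer(relax_steps), 1e-3, 0.05)
    pos <- res$pos
  }
  new_state(pos, system$box_edge, time = 0)
}

new_state <- function(pos_unwrapped, box, time = 0, vel = NULL) {
  img <- floor(pos_unwrapped / box)
  structure(list(time = time,
                 positions = pos_unwrapped - img * box,
                 images = img, velocities = vel, box_edge = box),
            class = "bd_state")
}

#' Unwrapped coordinates of a state
#' @param state a `bd_state`.
#' @return n x 3 matrix of unwrapped positions, sigma.
#' @export
unwrapped_positions <- function(state) {
  state$positions + state$images * state$box_edge
}

#' Run the binding protocol
#'
#' Integrates Langevin dynamics for `duration` time units.  Species'
#' affinities are off until their `activation_time` (the fiber equilibrates
#' as a self-avoiding chain first) and are then switched on; `schedule`
#' applies further affinity changes mid-run (a data.frame with columns
#' `time`, `species`, `bead_color`, `eps`).  The state is sampled every
#' `sample_every` time units.
#'
#' @param system a [bead_system()].
#' @param duration total simulated time, time units (tau).
#' @param dt integration time step, tau.
#' @param sample_every snapshot interval, tau.
#' @param seed integer master seed; placement and dynamics draw from
#'   deterministic streams derived from it.
#' @param state optional starting `bd_state` (default: a fresh
#'   [initialize_conformation()] under `seed`).
#' @param schedule optional mid-run affinity changes (see above).
#' @param phantom restrict steric interactions to bonded pairs (an ideal,
#'   non-self-avoiding chain; used to validate the realized persistence
#'   length against the discrete worm-like-chain prediction).
#' @return a `bd_trajectory`: `times`, `positions` (3 x n x n_snap array of
#'   unwrapped coordinates), the `system`, `dt`, `seed`, and the final
#'   `state`.
#' @export
run_protocol <- function(system, duration, dt = 0.01, sample_every = 1000,
                         seed = 1, state = NULL, schedule = NULL,
                         phantom = FALSE) {
  stopifnot(duration > 0, dt > 0, sample_every > 0)
  if (is.null(state)) state <- initialize_conformation(system, seed = seed)
  n_steps <- ceiling(duration / dt)
  ses <- max(1L, as.integer(round(sample_every / dt)))
  cfg <- engine_config(system, unwrapped_positions(state),
                       vel = state$velocities, dt = dt, seed = seed + 2,
                       n_steps = n_steps, sample_every_steps = ses,
                       schedule = schedule, phantom = phantom)
  res <- cpp_run(cfg)
  n <- system$n_particles
  nsnap <- length(res$times)
  posarr <- array(res$traj, dim = c(3, n, nsnap))
  structure(list(times = state$time + res$times, positions = posarr,
                 system = system, dt = dt, sample_every = sample_every,
                 seed = seed,
                 state = new_state(res$pos, system$box_edge,
                                   time = state$time + n_steps * dt,
                                   vel = res$vel)),
            class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d snapshots, t = %.4g .. %.4g tau (dt %.3g), %d particles\n",
              length(x$times), min(x$times), max(x$times), x$dt,
              x$system$n_particles))
  invisible(x)
}

#' Positions of one snapshot
#' @param traj a `bd_trajectory`.
#' @param i snapshot index (default: last).
#' @param wrap wrap into the periodic box.
#' @return n x 3 matrix, sigma.
#' @export
snapshot_positions <- function(traj, i = length(traj$times), wrap = FALSE) {
  p <- t(traj$positions[, , i])
  if (wrap) p <- p - floor(p / traj$system$box_edge) * traj$system$box_edge
  p
}

#' Advance a state by a few integration steps
#'
#' Thin wrapper over the integrator for stepwise use: advances `state` by
#' `n_steps` steps of size `dt` and returns the new `bd_state`.  Active
#' affinities follow the species' activation times relative to the state's
#' clock.
#'
#' @param system a [bead_system()].
#' @param state a `bd_state`.
#' @param dt time step, tau.
#' @param n_steps number of steps.
#' @param seed noise seed for this segment.
#' @return the advanced `bd_state`.
#' @export
bd_step <- function(system, state, dt = 0.01, n_steps = 1, seed = 1) {
  run_protocol(system, duration = n_steps * dt, dt = dt,
               sample_every = n_steps * dt, seed = seed, state = state)$state
}

#' Restrict a trajectory to a subset of snapshots
#' @param traj a `bd_trajectory`.
#' @param idx snapshot indices to keep.
#' @return the trajectory with only the selected snapshots.
#' @export
subset_snapshots <- function(traj, idx) {
  traj$times <- traj$times[idx]
  traj$positions <- traj$positions[, , idx, drop = FALSE]
  traj
}

#' Snapshot as a `bd_state`
#' @inheritParams snapshot_positions
#' @export
snapshot_state <- function(traj, i = length(traj$times)) {
  new_state(t(traj$positions[, , i]), traj$system$box_edge,
            time = traj$times[i])
}

#' All particle pairs within a cutoff (minimum image)
#'
#' Cell-list search over the periodic box; returns exactly the pairs with
#' minimum-image distance at most (`strict`: strictly below) `cutoff`, in
#' deterministic (i, j) order.
#'
#' @param positions n x 3 matrix (wrapped or unwrapped), or a `bd_state`.
#' @param cutoff distance cutoff, sigma; must be below half the box edge.
#' @param box_edge box edge, sigma (taken from the state if given).
#' @param strict use strict inequality (the clustering convention).
#' @return list with `pairs` (m x 2, 1-based) and `dist`.
#' @export
neighbor_search <- function(positions, cutoff, box_edge = NULL,
                            strict = FALSE) {
  if (inherits(positions, "bd_state")) {
    box_edge <- positions$box_edge
    positions <- positions$positions
  }
  stopifnot(!is.null(box_edge))
  cpp_pairs(positions, box_edge, cutoff, strict)
}

#' Forces and potential energy of a configuration
#'
#' Direct evaluation of the full force field (bonds, bending, sterics,
#' active attractions) on given coordinates; used for gradient checks and
#' zero-temperature relaxation tests.
#'
#' @param system a [bead_system()].
#' @param pos n x 3 positions, sigma (unwrapped or wrapped).
#' @param active_species species color labels whose affinities are on
#'   (default: all on).
#' @return list with `forces` (n x 3, kBT/sigma) and `energy` (kBT).
#' @export
system_forces <- function(system, pos, active_species = NULL) {
  cfg <- engine_config(system, pos)
  if (!is.null(active_species)) {
    off <- !(rownames(system$ff$affinity) %in% active_species)
    cfg$activation_step[off] <- .Machine$integer.max
  } else {
    cfg$activation_step <- rep(0L, length(cfg$activation_step))
  }
  cpp_forces(cfg)
}

#' Zero-temperature relaxation (displacement-capped steepest descent)
#'
#' @param system a [bead_system()].
#' @param pos starting positions (n x 3).
#' @param n_steps descent steps.
#' @param step_size multiplier on the force, sigma^2/kBT.
#' @param max_move per-component displacement cap, sigma.
#' @param bind apply active attractions (default) or sterics+bonds only.
#' @return list with final `pos`, `forces`, `energy`.
#' @export
relax_state <- function(system, pos, n_steps = 1000, step_size = 1e-3,
                        max_move = 0.05, bind = TRUE) {
  cfg <- engine_config(system, pos)
  cfg$activation_step <- rep(if (bind) 0L else .Machine$integer.max,
                             length(cfg$activation_step))
  cpp_relax(cfg, as.integer(n_steps), step_size, max_move)
}
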