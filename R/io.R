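#' Save / load trajectories
#'
#' Trajectories are stored as compressed RDS containers (positions, times,
#' system definition, seed); single snapshots can be exported as XYZ for
#' visualization.
#'
#' @param traj a `bd_trajectory`.
#' @param file path.
#' @export
write_trajectory <- function(traj, file) {
  saveRDS(traj, file, compress = "xz")
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  tr <- readRDS(file)
  if (!inherits(tr, "bd_trajectory")) stop("not a bd_trajectory file")
  tr
}

#' @rdname write_trajectory
#' @param i snapshot index.
#' @export
write_xyz <- function(traj, file, i = length(traj$times)) {
  sys <- traj$system
  p <- snapshot_positions(traj, i, wrap = TRUE)
  labels <- c(vapply(seq_len(sys$n_beads), function(b) {
    cols <- sys$palette[bitwAnd(sys$colorbits[b],
                bitwShiftL(1L, seq_along(sys$palette) - 1L)) > 0L]
    cols[1]
  }, character(1)),
  rownames(sys$ff$affinity)[sys$species[sys$species > 0L]])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(p)),
               sprintf("t=%g box=%g", traj$times[i], sys$box_edge)), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", labels, p[, 1], p[, 2], p[, 3]),
             con)
}

#' Structured run log
#'
#' One-call provenance record: resolved configuration, realized affinity
#' well depths (epsilon minus the cutoff shift), seed and timing.
#'
#' @param traj a `bd_trajectory`.
#' @return character vector of log lines (also suitable for `writeLines`).
#' @export
run_log <- function(traj) {
  sys <- traj$system
  ff <- sys$ff
  shift <- 4 * ((1 / ff$attraction_cutoff)^12 - (1 / ff$attraction_cutoff)^6)
  lines <- c(
    sprintf("chromobridge run log"),
    sprintf("seed: %d", traj$seed),
    sprintf("particles: %d beads + %d factors, box %.6g sigma",
            sys$n_beads, sys$n_factors, sys$box_edge),
    sprintf("dt: %g tau, sampled every %g tau, %d snapshots",
            traj$dt, traj$sample_every, length(traj$times)),
    sprintf("force field: FENE k=%g R0=%g, WCA eps=%g, cutoff %g sigma",
            ff$fene_k, ff$fene_r0, ff$eps_steric, ff$attraction_cutoff),
    sprintf("time unit: %.4g ms", physical_time_unit(sys$units)))
  for (sp in rownames(ff$affinity)) for (bc in colnames(ff$affinity)) {
    e <- ff$affinity[sp, bc]
    if (e > 0)
      lines <- c(lines, sprintf(
        "affinity %s->%s: epsilon %.4g kBT (realized well depth %.4g kBT)",
        sp, bc, e, e * (1 + shift)))
  }
  lines
}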