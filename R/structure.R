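#' Single-linkage clusters of factors and/or binding beads
#'
#' Two participants belong to the same cluster when their centers lie
#' strictly within `cutoff` (minimum-image; single-linkage connected
#' components, so a chain of close particles is one cluster).  Clusters are
#' groups of two or more; singletons are excluded from the cluster list but
#' counted in the fractions.
#'
#' @param state a `bd_state` or an n x 3 position matrix.
#' @param system the [bead_system()] (for participant lookup and colors).
#' @param participants which particles to cluster: `"factors"` (all factor
#'   spheres), `"bound_factors"` (factors within the attraction cutoff of a
#'   cognate bead), `"strongly_bound_factors"` (factors at a bead carrying
#'   their species' strongest affinity — bound to a proper binding site,
#'   not merely held by non-specific attraction), `"binding_beads"` (beads
#'   any species binds), `"high_affinity_beads"`, a species color (its
#'   factors), a bead color (e.g. `"pink"`), or an integer vector of
#'   particle indices.
#' @param cutoff_nm linkage cutoff in nm (default 90 nm, i.e. 3 sigma for
#'   30-nm beads).
#' @return an object of class `cluster_set`: list with `members` (list of
#'   integer vectors, particle indices), `participant_ids`, `colors` (per
#'   cluster: member color labels), `dominant_color`, `purity`, `time`.
#' @export
find_clusters <- function(state, system, participants = "factors",
                          cutoff_nm = 90) {
  pos <- if (inherits(state, "bd_state")) state$positions else state
  box <- system$box_edge
  cutoff <- cutoff_nm / system$units$sigma_nm
  if (cutoff >= box / 2)
    stop("cluster cutoff must be below half the box edge")
  ids <- participant_ids(system, participants, pos)
  if (!length(ids)) {
    return(empty_cluster_set(ids,
      time = if (inherits(state, "bd_state")) state$time else NA_real_))
  }
  sub <- pos[ids, , drop = FALSE]
  nb <- cpp_pairs(sub, box, cutoff, TRUE)
  comp <- cpp_components(length(ids), nb$pairs)
  tab <- table(comp)
  keep <- as.integer(names(tab)[tab >= 2])
  members <- lapply(keep, function(k) ids[comp == k])
  # order clusters by smallest member id for reproducibility
  if (length(members)) members <- members[order(vapply(members, min, 1L))]
  cols <- lapply(members, function(m) particle_colors(system, m, pos))
  purity <- vapply(cols, function(cc) {
    if (!length(cc)) return(NA_real_)
    max(table(cc)) / length(cc)
  }, numeric(1))
  dom <- vapply(cols, function(cc) {
    if (!length(cc)) return(NA_character_)
    names(sort(table(cc), decreasing = TRUE))[1]
  }, character(1))
  structure(list(members = members, participant_ids = ids,
                 colors = cols, dominant_color = dom, purity = purity,
                 cutoff_nm = cutoff_nm,
                 time = if (inherits(state, "bd_state")) state$time else NA_real_),
            class = "cluster_set")
}

empty_cluster_set <- function(ids, time = NA_real_) {
  structure(list(members = list(), participant_ids = ids,
                 colors = list(), dominant_color = character(0),
                 purity = numeric(0), cutoff_nm = NA_real_, time = time),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sz <- lengths(x$members)
  cat(sprintf("cluster set (t = %.4g): %d cluster(s) of >= 2 among %d participants\n",
              x$time, length(sz), length(x$participant_ids)))
  if (length(sz))
    cat(sprintf("  mean size %.3g, max %d, fraction clustered %.3g\n",
                mean(sz), max(sz), sum(sz) / length(x$participant_ids)))
  invisible(x)
}

# resolve a participant specification to particle indices
participant_ids <- function(system, participants, pos = NULL) {
  n_beads <- system$n_beads
  if (is.numeric(participants)) return(as.integer(participants))
  if (length(participants) == 1 && participants %in%
      rownames(system$ff$affinity)) {
    si <- match(participants, rownames(system$ff$affinity))
    return(which(system$species == si))
  }
  if (length(participants) == 1 && participants %in% system$palette &&
      !(participants %in% c("factors", "bound_factors", "binding_beads",
                            "high_affinity_beads"))) {
    mask <- bitwShiftL(1L, match(participants, system$palette) - 1L)
    return(which(bitwAnd(c(system$colorbits,
                           rep(0L, system$n_factors)), mask) > 0L))
  }
  switch(participants,
    factors = which(system$species > 0L),
    bound_factors = {
      stopifnot(!is.null(pos))
      which(bound_factor_flags(system, pos))
    },
    strongly_bound_factors = {
      stopifnot(!is.null(pos))
      which(bound_factor_flags(system, pos, high_only = TRUE))
    },
    binding_beads = which(binding_beads(system)),
    high_affinity_beads = which(binding_beads(system, high_only = TRUE)),
    stop("unknown participant set: ", participants))
}

# logical over all particles: factor currently within the attraction cutoff
# of a cognate bead (high_only: of a bead carrying the species' strongest
# affinity color, i.e. bound to a proper binding site rather than held by
# non-specific attraction)
bound_factor_flags <- function(system, pos, high_only = FALSE) {
  out <- rep(FALSE, system$n_particles)
  fac <- which(system$species > 0L)
  if (!length(fac)) return(out)
  rc <- system$ff$attraction_cutoff * max(system$diam)
  nb <- cpp_pairs(pos, system$box_edge, rc, FALSE)
  p <- nb$pairs
  if (!nrow(p)) return(out)
  eps <- system$ff$affinity
  for (k in seq_len(nrow(p))) {
    a <- p[k, 1]; b <- p[k, 2]
    f <- if (system$species[a] > 0L && system$species[b] == 0L) a
         else if (system$species[b] > 0L && system$species[a] == 0L) b
         else next
    bead <- if (f == a) b else a
    si <- system$species[f]
    cols <- system$palette[bitwAnd(system$colorbits[bead],
                                   bitwShiftL(1L, seq_along(system$palette) - 1L)) > 0L]
    e <- if (length(cols)) max(eps[si, cols]) else 0
    emin <- if (high_only) max(eps[si, ]) else .Machine$double.eps
    sig <- (system$diam[f] + system$diam[bead]) / 2
    if (e >= emin && e > 0 && nb$dist[k] <= system$ff$attraction_cutoff * sig)
      out[f] <- TRUE
  }
  out
}

# color labels of particles: species color for factors, bead color(s)
# collapsed to the bound-factor color for multi-color beads
particle_colors <- function(system, ids, pos = NULL) {
  vapply(ids, function(i) {
    if (system$species[i] > 0L)
      return(rownames(system$ff$affinity)[system$species[i]])
    cols <- system$palette[bitwAnd(system$colorbits[i],
                bitwShiftL(1L, seq_along(system$palette) - 1L)) > 0L]
    cols[1]
  }, character(1))
}

#' Export a cluster set as TSV
#'
#' One row per cluster: id, size, dominant color, purity, comma-separated
#' member particle ids.
#'
#' @param clusters a `cluster_set`.
#' @param file output path.
#' @export
write_cluster_set <- function(clusters, file) {
  df <- data.frame(
    cluster = seq_along(clusters$members),
    size = lengths(clusters$members),
    dominant_color = clusters$dominant_color,
    purity = clusters$purity,
    members = vapply(clusters$members, paste, character(1), collapse = ","))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Cluster-size and clustered-fraction time series
#'
#' Per snapshot: the mean size of clusters with at least two members (1 when
#' there is none) and the fraction of participants that belong to any such
#' cluster.  Steady-state summaries average over the final `steady_window`
#' fraction of snapshots.
#'
#' @param traj a `bd_trajectory`.
#' @param participants see [find_clusters()].
#' @param cutoff_nm linkage cutoff, nm.
#' @param steady_window final fraction of snapshots regarded as steady state.
#' @return a data.frame with `time`, `mean_size`, `fraction_clustered`,
#'   `n_clusters`; steady-state means in attributes `steady_mean_size` and
#'   `steady_fraction`.
#' @export
cluster_timeseries <- function(traj, participants = "factors",
                               cutoff_nm = 90, steady_window = 0.2) {
  nt <- length(traj$times)
  res <- lapply(seq_len(nt), function(i) {
    st <- snapshot_state(traj, i)
    cs <- find_clusters(st, traj$system, participants, cutoff_nm)
    sz <- lengths(cs$members)
    data.frame(time = traj$times[i],
               mean_size = if (length(sz)) mean(sz) else 1,
               fraction_clustered = if (length(cs$participant_ids))
                 sum(sz) / length(cs$participant_ids) else 0,
               n_clusters = length(sz))
  })
  out <- do.call(rbind, res)
  iss <- seq.int(max(1L, ceiling(nt * (1 - steady_window))), nt)
  attr(out, "steady_mean_size") <- mean(out$mean_size[iss])
  attr(out, "steady_fraction") <- mean(out$fraction_clustered[iss])
  out
}

#' Color purity of clusters
#'
#' Purity of a cluster is the fraction of members carrying its most common
#' color.  The summary reports, over clusters of two or more, the fraction
#' that are pure (one color only) and the fraction with purity >= 0.8.
#'
#' @param clusters a `cluster_set` from [find_clusters()].
#' @return list with `purity` (per cluster), `fraction_pure`,
#'   `fraction_ge80`.
#' @export
cluster_purity <- function(clusters) {
  p <- clusters$purity
  list(purity = p,
       fraction_pure = if (length(p)) mean(p == 1) else NA_real_,
       fraction_ge80 = if (length(p)) mean(p > 0.8) else NA_real_)
}

#' Rosettogram: cluster-by-binding-bead incidence
#'
#' One row per cluster (ordered along the fiber by first member bead), one
#' column per high-affinity bead in fiber order; entry `i, j` is the color
#' index (or 1 for single-species systems) when high-affinity bead j belongs
#' to cluster i, 0 otherwise.  Runs of abutting nonzero pixels in a row are
#' rosette "petals" anchored at consecutive binding sites.
#'
#' @param clusters a `cluster_set` whose participants include the
#'   high-affinity beads (e.g. from participants = "high_affinity_beads" or
#'   a mixed bead+factor clustering).
#' @param system the [bead_system()].
#' @param state optional `bd_state` used to color pixels by the nearest
#'   bound factor's species in multi-species systems.
#' @return object of class `rosettogram`: `incidence` matrix, `bead_ids`
#'   (column particle ids), `f_d` (disorganized fraction).
#' @export
rosettogram <- function(clusters, system, state = NULL) {
  hi <- which(binding_beads(system, high_only = TRUE))
  inc <- matrix(0L, nrow = length(clusters$members), ncol = length(hi))
  colnames(inc) <- hi
  pal <- rownames(system$ff$affinity)
  for (ci in seq_along(clusters$members)) {
    m <- intersect(clusters$members[[ci]], hi)
    if (!length(m)) next
    val <- 1L
    if (!is.null(state) && length(pal) > 1) {
      for (b in m) {
        sp <- nearest_bound_species(system, state, b)
        inc[ci, match(b, hi)] <- if (is.na(sp)) 1L else sp
      }
      next
    }
    inc[ci, match(m, hi)] <- val
  }
  keep <- rowSums(inc != 0L) > 0L
  inc <- inc[keep, , drop = FALSE]
  if (nrow(inc) > 1) {
    first <- apply(inc, 1, function(r) which(r != 0L)[1])
    inc <- inc[order(first), , drop = FALSE]
  }
  structure(list(incidence = inc, bead_ids = hi,
                 f_d = disorganized_fraction(clusters, system)),
            class = "rosettogram")
}

#' @export
print.rosettogram <- function(x, ...) {
  cat(sprintf("rosettogram: %d cluster row(s) x %d high-affinity beads, f_d = %.3g\n",
              nrow(x$incidence), ncol(x$incidence), x$f_d))
  invisible(x)
}

# species index of the factor nearest to bead b (within attraction cutoff),
# ties broken by smaller species index; NA if none
nearest_bound_species <- function(system, state, b) {
  pos <- state$positions
  fac <- which(system$species > 0L)
  if (!length(fac)) return(NA_integer_)
  d <- minimum_image_dist(pos[b, , drop = FALSE], pos[fac, , drop = FALSE],
                          system$box_edge)
  sig <- (system$diam[b] + system$diam[fac]) / 2
  ok <- d <= system$ff$attraction_cutoff * sig
  if (!any(ok)) return(NA_integer_)
  cand <- fac[ok]
  dc <- d[ok]
  best <- order(dc, system$species[cand])[1]
  system$species[cand[best]]
}

minimum_image_dist <- function(a, b, box) {
  d <- sweep(b, 2, as.numeric(a))
  d <- d - box * round(d / box)
  sqrt(rowSums(d^2))
}

#' Disorganized fraction f_d
#'
#' The fraction of high-affinity beads that do NOT share a cluster with
#' either of their nearest-neighbor high-affinity beads along the fiber
#' (beads in no cluster count as not sharing).  Low f_d means rosette-like,
#' locally organized folding; f_d plus the neighbor-sharing fraction is 1 by
#' construction.
#'
#' @param clusters a `cluster_set` over (at least) the high-affinity beads.
#' @param system the [bead_system()].
#' @return f_d in `[0, 1]`.
#' @export
disorganized_fraction <- function(clusters, system) {
  hi <- which(binding_beads(system, high_only = TRUE))
  if (length(hi) < 2) stop("need at least two high-affinity beads")
  lab <- rep(NA_integer_, system$n_particles)
  for (ci in seq_along(clusters$members))
    lab[clusters$members[[ci]]] <- ci
  # fiber-order neighbors among high-affinity beads, same fiber only
  fid <- system$fiber_id[hi]
  shares <- vapply(seq_along(hi), function(k) {
    b <- hi[k]
    if (is.na(lab[b])) return(FALSE)
    nb <- c(if (k > 1 && fid[k - 1] == fid[k]) hi[k - 1],
            if (k < length(hi) && fid[k + 1] == fid[k]) hi[k + 1])
    any(!is.na(lab[nb]) & lab[nb] == lab[b])
  }, logical(1))
  1 - mean(shares)
}

#' Radius of gyration time series
#'
#' Standard Rg over a particle subset per snapshot, computed from unwrapped
#' coordinates (a straight rod of N beads at unit spacing has
#' Rg = sqrt((N^2 - 1) / 12)).
#'
#' @param traj a `bd_trajectory`.
#' @param subset particle indices (default: all beads).
#' @param steady_window final fraction of snapshots for the steady-state
#'   summary.
#' @return data.frame `time`, `rg`; attributes `steady_rg` and
#'   `steady_drift` (relative drift of the final-window linear fit).
#' @export
radius_of_gyration <- function(traj, subset = NULL,
                               steady_window = 0.25) {
  if (is.null(subset)) subset <- seq_len(traj$system$n_beads)
  rg <- vapply(seq_along(traj$times), function(i) {
    p <- t(traj$positions[, subset, i])
    cm <- colMeans(p)
    sqrt(mean(rowSums(sweep(p, 2, cm)^2)))
  }, numeric(1))
  out <- data.frame(time = traj$times, rg = rg)
  nt <- length(rg)
  iss <- seq.int(max(1L, ceiling(nt * (1 - steady_window))), nt)
  attr(out, "steady_rg") <- mean(rg[iss])
  if (length(iss) >= 3) {
    fit <- stats::lm(rg[iss] ~ traj$times[iss])
    drift <- stats::coef(fit)[2] * diff(range(traj$times[iss]))
    attr(out, "steady_drift") <- abs(drift) / mean(rg[iss])
  } else attr(out, "steady_drift") <- NA_real_
  out
}
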