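#' Hi-C-like contact map from a trajectory
#'
#' For every snapshot, each bead pair with minimum-image center distance at
#' or below `threshold_nm` scores one contact; counts are accumulated over
#' snapshots into bins of `bin_beads` adjacent beads (the unbinned,
#' high-resolution variant uses `bin_beads = 1`, conventionally with a 90-nm
#' threshold).  Each bead also scores a self-contact so the diagonal is
#' maximal in unnormalized maps.
#'
#' @param traj a `bd_trajectory`.
#' @param threshold_nm contact distance threshold, nm (inclusive).
#' @param bin_beads beads per bin.
#' @param beads bead subset (default: all beads, in fiber order).
#' @param snapshots snapshot indices to aggregate (default: all).
#' @return object of class `contact_map`: `counts` (symmetric matrix),
#'   `bin_beads`, `threshold_nm`, `n_snapshots`, `beads`.
#' @export
contact_map <- function(traj, threshold_nm = 150, bin_beads = 40,
                        beads = NULL, snapshots = NULL) {
  sys <- traj$system
  thr <- threshold_nm / sys$units$sigma_nm
  if (thr >= sys$box_edge / 2) stop("contact threshold must be below half the box edge")
  if (is.null(beads)) beads <- seq_len(sys$n_beads)
  if (is.null(snapshots)) snapshots <- seq_along(traj$times)
  sub <- traj$positions[, beads, snapshots, drop = FALSE]
  m <- matrix(sub, nrow = 3 * length(beads), ncol = length(snapshots))
  counts <- cpp_contact_map(m, length(beads), sys$box_edge, thr,
                            as.integer(bin_beads))
  structure(list(counts = counts, bin_beads = as.integer(bin_beads),
                 threshold_nm = threshold_nm,
                 n_snapshots = length(snapshots), beads = beads),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact map: %d x %d bins (%d beads/bin), threshold %.4g nm, %d snapshot(s)\n",
              nrow(x$counts), ncol(x$counts), x$bin_beads, x$threshold_nm,
              x$n_snapshots))
  invisible(x)
}

#' Construct a contact map from a plain matrix
#'
#' Wraps an existing symmetric count matrix (e.g. read from a dense TSV or
#' built synthetically) as a `contact_map` so the boundary-detection
#' operations can be applied to it.
#'
#' @param counts symmetric nonnegative matrix.
#' @param bin_beads beads per bin (metadata).
#' @param threshold_nm contact threshold metadata.
#' @param n_snapshots aggregation metadata.
#' @export
as_contact_map <- function(counts, bin_beads = 1L, threshold_nm = NA_real_,
                           n_snapshots = 1L) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (max(abs(counts - t(counts))) > 1e-8) stop("contact matrix must be symmetric")
  structure(list(counts = counts, bin_beads = as.integer(bin_beads),
                 threshold_nm = threshold_nm, n_snapshots = n_snapshots,
                 beads = seq_len(nrow(counts) * bin_beads)),
            class = "contact_map")
}

#' Read / write dense contact maps as TSV
#'
#' The first line is a header comment `# bin_beads=<b> threshold_nm=<t>
#' n_snapshots=<n>`; the body is the dense count matrix.
#'
#' @param map a `contact_map`.
#' @param file path.
#' @export
write_contact_map <- function(map, file) {
  hdr <- sprintf("# bin_beads=%d threshold_nm=%s n_snapshots=%d",
                 map$bin_beads, format(map$threshold_nm), map$n_snapshots)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(map$counts, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(file) {
  hdr <- readLines(file, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  counts <- as.matrix(utils::read.table(file, skip = 1, sep = "\t"))
  dimnames(counts) <- NULL
  as_contact_map(counts,
                 bin_beads = as.integer(meta[["bin_beads"]]),
                 threshold_nm = suppressWarnings(
                   as.numeric(meta[["threshold_nm"]])),
                 n_snapshots = as.integer(meta[["n_snapshots"]]))
}

#' Fraction of contacts joining different fibers
#'
#' Computed over all snapshots for two participant sets: all beads, and
#' binding beads that are currently in clusters (the spec of active
#' genomic regions concentrated in factor clusters).
#'
#' @param traj a `bd_trajectory` of a multi-fiber system.
#' @param threshold_nm contact threshold, nm.
#' @param cluster_cutoff_nm linkage cutoff used to decide "in a cluster".
#' @return list with `all_beads` and `binding_in_clusters` fractions.
#' @export
inter_fiber_contact_fraction <- function(traj, threshold_nm = 150,
                                         cluster_cutoff_nm = 90) {
  sys <- traj$system
  if (length(sys$fibers) < 2) stop("need at least two fibers")
  thr <- threshold_nm / sys$units$sigma_nm
  frac <- function(ids_per_snap) {
    tot <- 0; inter <- 0
    for (i in seq_along(traj$times)) {
      ids <- ids_per_snap(i)
      if (length(ids) < 2) next
      p <- t(traj$positions[, ids, i])
      nb <- cpp_pairs(p, sys$box_edge, thr, FALSE)
      if (!nrow(nb$pairs)) next
      fa <- sys$fiber_id[ids[nb$pairs[, 1]]]
      fb <- sys$fiber_id[ids[nb$pairs[, 2]]]
      tot <- tot + nrow(nb$pairs)
      inter <- inter + sum(fa != fb)
    }
    if (tot == 0) 0 else inter / tot
  }
  all_f <- frac(function(i) seq_len(sys$n_beads))
  bb <- which(binding_beads(sys))
  clus_f <- frac(function(i) {
    st <- snapshot_state(traj, i)
    cs <- find_clusters(st, sys, participants = bb,
                        cutoff_nm = cluster_cutoff_nm)
    intersect(unlist(cs$members), bb)
  })
  list(all_beads = all_f, binding_in_clusters = clus_f)
}

#' Contact probability versus genomic separation
#'
#' P(s): the probability that two beads of the same fiber separated by s
#' beads are in contact (distance at or below the threshold), averaged over
#' bead pairs and snapshots.
#'
#' @param traj a `bd_trajectory`.
#' @param threshold_nm contact threshold, nm.
#' @param max_sep largest separation, beads (default: longest fiber - 1).
#' @return data.frame with `s` (beads) and `p`.
#' @export
contact_probability <- function(traj, threshold_nm = 150, max_sep = NULL) {
  sys <- traj$system
  thr <- threshold_nm / sys$units$sigma_nm
  lens <- vapply(sys$fibers, `[[`, integer(1), "n_beads")
  if (is.null(max_sep)) max_sep <- max(lens) - 1L
  beads <- seq_len(sys$n_beads)
  m <- matrix(traj$positions[, beads, , drop = FALSE],
              nrow = 3 * length(beads), ncol = length(traj$times))
  res <- cpp_contact_by_sep(m, length(beads), sys$box_edge, thr,
                            sys$fiber_id, sys$idx_in_fiber,
                            as.integer(max_sep))
  # number of same-fiber pairs at each separation
  npair <- vapply(0:max_sep, function(s) sum(pmax(lens - s, 0)), numeric(1))
  s <- 1:max_sep
  p <- (res$counts[s + 1] / res$n_snapshots) / npair[s + 1]
  data.frame(s = s, p = p)
}

#' Power-law fit of the contact-probability decay
#'
#' Least-squares fit of log P(s) = alpha log s + c over a separation range;
#' used to read off the intra-domain (alpha between -1 and -0.6) and
#' inter-domain (alpha near -2) regimes.  Degenerate input (fewer than 3
#' usable points or zero probabilities throughout, e.g. the step-function
#' P(s) of a rigid rod) is rejected with a diagnostic.
#'
#' @param ps data.frame from [contact_probability()].
#' @param s_range numeric length-2: fit range in beads (inclusive).
#' @return object of class `scaling_fit`: `alpha`, `se`, `s_range`,
#'   `n_points`, and the underlying `lm` fit.
#' @export
fit_scaling <- function(ps, s_range) {
  stopifnot(length(s_range) == 2, s_range[1] < s_range[2])
  sel <- ps$s >= s_range[1] & ps$s <= s_range[2] & ps$p > 0
  if (sum(sel) < 3)
    stop("degenerate P(s): fewer than 3 positive points in fit range [",
         s_range[1], ", ", s_range[2], "]")
  d <- ps[sel, ]
  # reject a step-like P(s) (rod): all probabilities equal
  if (stats::sd(log(d$p)) < 1e-12)
    stop("degenerate P(s): no decay over the fit range (step function)")
  fit <- stats::lm(log(p) ~ log(s), data = d)
  structure(list(alpha = unname(stats::coef(fit)[2]),
                 se = summary(fit)$coefficients[2, 2],
                 s_range = s_range, n_points = nrow(d), fit = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("P(s) ~ s^alpha: alpha = %.3f +/- %.3f (s in [%g, %g], %d points)\n",
              x$alpha, x$se, x$s_range[1], x$s_range[2], x$n_points))
  invisible(x)
}

#' Janus profiles, difference plot and insulation signal
#'
#' For each bin i, the Janus profiles sum the contacts i makes with bins up
#' to `window` bins to its left and to its right; the difference plot is
#' right minus left.  At a domain boundary a bin switches from mostly
#' leftward to mostly rightward contacts, so the difference crosses zero
#' with positive slope; the first derivative of the (smoothed) difference is
#' the insulation signal whose peaks give a sharper boundary position.
#'
#' @param map a `contact_map`.
#' @param window window, bins.
#' @param smooth moving-average width (bins) applied to the difference
#'   before derivative/zero-crossing detection; 1 = none.
#' @return data.frame with `bin`, `left`, `right`, `difference`,
#'   `difference_smooth`, `insulation`.
#' @export
janus_profiles <- function(map, window = 10, smooth = 5) {
  M <- map$counts
  n <- nrow(M)
  if (window < 1 || window >= n) stop("window must be in [1, bins-1]")
  left <- numeric(n)
  right <- numeric(n)
  for (i in seq_len(n)) {
    jl <- seq.int(max(1, i - window), i - 1)
    jr <- seq.int(i + 1, min(n, i + window))
    left[i] <- if (i > 1) sum(M[i, jl]) else 0
    right[i] <- if (i < n) sum(M[i, jr]) else 0
  }
  d <- right - left
  ds <- moving_average(d, smooth)
  ins <- c(NA, diff(ds))
  data.frame(bin = seq_len(n), left = left, right = right, difference = d,
             difference_smooth = ds, insulation = ins)
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- seq.int(max(1, i - (k %/% 2)), min(n, i + (k %/% 2)))
    mean(x[j])
  }, numeric(1))
}

#' Domain-boundary detection on a contact map
#'
#' `difference-zero-crossing`: bins where the smoothed difference plot
#' crosses zero with positive slope.  `insulation-peak`: local maxima of the
#' insulation signal (derivative of the smoothed difference).  Positions are
#' returned in beads (bin centers at the crossing).  An empty result is
#' valid (e.g. a single-domain map).
#'
#' @param map a `contact_map`.
#' @param method `"difference-zero-crossing"` or `"insulation-peak"`.
#' @param window Janus window, bins.
#' @param smooth moving-average width, bins.
#' @param min_strength discard boundaries whose local slope (difference
#'   method) or peak height (insulation method) is below this fraction of
#'   the strongest one.
#' @return object of class `boundary_set`: data.frame `position` (beads,
#'   sorted, deduplicated), `bin`, `score`; attributes `method`, `window`.
#' @export
find_boundaries <- function(map, method = c("difference-zero-crossing",
                                            "insulation-peak"),
                            window = 10, smooth = 5, min_strength = 0.2) {
  method <- match.arg(method)
  jp <- janus_profiles(map, window = window, smooth = smooth)
  ds <- jp$difference_smooth
  n <- length(ds)
  pos <- integer(0)
  score <- numeric(0)
  if (method == "difference-zero-crossing") {
    for (i in seq_len(n - 1)) {
      if (ds[i] < 0 && ds[i + 1] >= 0) {
        pos <- c(pos, i)
        score <- c(score, ds[i + 1] - ds[i])
      }
    }
  } else {
    ins <- jp$insulation
    for (i in 3:(n - 1)) {
      if (!anyNA(ins[(i - 1):(i + 1)]) &&
          ins[i] > ins[i - 1] && ins[i] >= ins[i + 1] && ins[i] > 0) {
        pos <- c(pos, i)
        score <- c(score, ins[i])
      }
    }
  }
  if (length(score) && min_strength > 0) {
    keep <- score >= min_strength * max(score)
    pos <- pos[keep]
    score <- score[keep]
  }
  bead_pos <- pos * map$bin_beads          # bead index at the bin junction
  out <- data.frame(position = bead_pos, bin = pos, score = score)
  out <- out[!duplicated(out$position), , drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  structure(out, class = c("boundary_set", "data.frame"),
            method = method, window = window)
}

#' Boundary concordance between two boundary lists
#'
#' Greedy nearest-first one-to-one matching: candidate pairs (a in `setA`,
#' b in `setB`) within `tolerance` are accepted in order of increasing
#' distance, each boundary used at most once.  Returns the fraction of
#' `setB` (the reference) recovered by `setA`, plus an optional permutation
#' null (uniformly replaced boundaries, same count).
#'
#' @param setA query positions (numeric vector or `boundary_set`).
#' @param setB reference positions.
#' @param tolerance matching tolerance (same units as the positions, e.g.
#'   bp; the genome-scale convention is 100 kbp).
#' @param span length-2 range used for the permutation null (default: range
#'   of both sets); `n_null = 0` skips the null.
#' @param n_null permutation-null replicates.
#' @param seed seed for the null.
#' @return list with `fraction_recovered`, `n_matched`, `matches`
#'   (data.frame), and `null_mean`/`null_sd` when requested.
#' @export
boundary_concordance <- function(setA, setB, tolerance, span = NULL,
                                 n_null = 0, seed = 1) {
  a <- boundary_positions(setA)
  b <- boundary_positions(setB)
  res <- greedy_match(a, b, tolerance)
  out <- list(fraction_recovered = if (length(b)) res$n / length(b) else NA_real_,
              n_matched = res$n, matches = res$matches)
  if (n_null > 0) {
    if (is.null(span)) span <- range(c(a, b))
    nulls <- with_seed(seed, vapply(seq_len(n_null), function(k) {
      a0 <- stats::runif(length(a), span[1], span[2])
      greedy_match(a0, b, tolerance)$n / length(b)
    }, numeric(1)))
    out$null_mean <- mean(nulls)
    out$null_sd <- stats::sd(nulls)
  }
  out
}

boundary_positions <- function(x) {
  if (inherits(x, "boundary_set")) return(x$position)
  as.numeric(x)
}

greedy_match <- function(a, b, tol) {
  if (!length(a) || !length(b))
    return(list(n = 0L, matches = data.frame(a = numeric(0), b = numeric(0),
                                             dist = numeric(0))))
  cand <- expand.grid(ia = seq_along(a), ib = seq_along(b))
  cand$dist <- abs(a[cand$ia] - b[cand$ib])
  cand <- cand[cand$dist <= tol, , drop = FALSE]
  cand <- cand[order(cand$dist), , drop = FALSE]
  useda <- logical(length(a))
  usedb <- logical(length(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!useda[cand$ia[k]] && !usedb[cand$ib[k]]) {
      keep[k] <- TRUE
      useda[cand$ia[k]] <- TRUE
      usedb[cand$ib[k]] <- TRUE
    }
  }
  m <- cand[keep, , drop = FALSE]
  list(n = nrow(m),
       matches = data.frame(a = a[m$ia], b = b[m$ib], dist = m$dist))
}

#' Boundary sets as BED
#'
#' @param bs a `boundary_set` (positions interpreted in bp when `bead_bp`
#'   given, else beads).
#' @param file path.
#' @param chrom chromosome label.
#' @param bead_bp bp per bead for coordinate conversion (1 = already bp).
#' @export
write_boundaries_bed <- function(bs, file, chrom = "chrSim", bead_bp = 1) {
  p <- round(boundary_positions(bs) * bead_bp)
  df <- data.frame(chrom = chrom, start = p, end = p + 1,
                   name = sprintf("boundary_%d", seq_along(p)))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}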