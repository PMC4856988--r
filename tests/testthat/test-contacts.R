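# Contact maps, P(s) scaling, Janus/difference boundaries, concordance.

rod_trajectory <- function(N = 200, box = 300, spacing = 1) {
  sys <- bead_system(toy_fiber(N, "regular", every = 20), list(),
                     box_edge = box)
  rod <- cbind(seq_len(N) * spacing, 0.5, 0.5)
  tr <- list(times = 0, positions = array(t(rod), dim = c(3, N, 1)),
             system = sys, dt = 0.01, sample_every = 1, seed = 1)
  class(tr) <- "bd_trajectory"
  tr
}

test_that("rod geometry: contacts only within the threshold separation", {
  tr <- rod_trajectory(200)
  m <- contact_map(tr, threshold_nm = 5 * 30, bin_beads = 1)
  idx <- which(m$counts > 0, arr.ind = TRUE)
  expect_true(all(abs(idx[, 1] - idx[, 2]) <= 5))
  # bonded neighbors always in contact at 150 nm (1 sigma apart)
  expect_true(all(m$counts[cbind(1:199, 2:200)] > 0))
  # symmetric, nonnegative, maximal diagonal
  expect_true(all(m$counts == t(m$counts)))
  expect_true(all(diag(m$counts) >= apply(m$counts, 1, max)))
})

test_that("contact map equals a brute-force oracle and conserves binning", {
  set.seed(5)
  sys <- bead_system(toy_fiber(200, "regular", every = 20), list(),
                     box_edge = 40)
  st <- initialize_conformation(sys, seed = 3)
  tr <- run_protocol(sys, duration = 50, sample_every = 50, seed = 3,
                     state = st)
  thr_sigma <- 150 / 30
  m1 <- contact_map(tr, 150, bin_beads = 1, snapshots = 2)
  # oracle: all-pairs minimum image on the same snapshot
  pos <- snapshot_positions(tr, 2)
  d <- brute_dist_matrix(pos, 40)
  want <- (d <= thr_sigma) * 1
  expect_equal(unname(m1$counts - diag(1, 200)), unname(want - diag(1, 200)))
  # binning conserves total counts
  m40 <- contact_map(tr, 150, bin_beads = 40, snapshots = 2)
  expect_equal(sum(m40$counts), sum(m1$counts))
  # aggregation over snapshots is order-free
  ma <- contact_map(tr, 150, bin_beads = 20)
  expect_equal(ma$counts,
               contact_map(tr, 150, bin_beads = 20,
                           snapshots = rev(seq_along(tr$times)))$counts)
})

test_that("contact map round-trips through TSV", {
  m <- block_contact_map(30, 15)
  tf <- tempfile(fileext = ".tsv")
  write_contact_map(m, tf)
  m2 <- read_contact_map(tf)
  expect_equal(m2$counts, m$counts, tolerance = 1e-12)
  expect_equal(m2$bin_beads, m$bin_beads)
})

test_that("inter-fiber contact fractions: separated vs interdigitated", {
  f1 <- toy_fiber(50, "regular", every = 10)
  f2 <- toy_fiber(50, "regular", every = 10)
  sys <- bead_system(list(f1, f2), list(), box_edge = 200)
  # two well-separated straight rods
  rodA <- cbind(seq_len(50), 10, 10)
  rodB <- cbind(seq_len(50), 150, 150)
  tr <- list(times = 0,
             positions = array(t(rbind(rodA, rodB)), dim = c(3, 100, 1)),
             system = sys, dt = 0.01, sample_every = 1, seed = 1)
  class(tr) <- "bd_trajectory"
  res <- inter_fiber_contact_fraction(tr)
  expect_equal(res$all_beads, 0)
  # interdigitated rods 0.9 sigma apart: cross contacts dominate at 1 sigma
  rodB2 <- cbind(seq_len(50) + 0.5, 10.9, 10)
  tr2 <- tr
  tr2$positions <- array(t(rbind(rodA, rodB2)), dim = c(3, 100, 1))
  res2 <- inter_fiber_contact_fraction(tr2, threshold_nm = 1.1 * 30)
  expect_gt(res2$all_beads, 0.4)
  expect_error(inter_fiber_contact_fraction(
    list(times = 0, system = bead_system(f1, list(), box_edge = 50))),
    "two fibers")
})

test_that("random-walk ensemble gives the -3/2 contact-probability exponent", {
  # ideal-chain oracle: P(contact at separation s) ~ s^(-3/2)
  set.seed(99)
  n <- 400; chains <- 60; rc <- 1.2
  counts <- numeric(n); tries <- numeric(n)
  for (c in seq_len(chains)) {
    steps <- matrix(rnorm(n * 3, sd = 1 / sqrt(3)), ncol = 3)
    pos <- apply(steps, 2, cumsum)
    for (s in c(8, 12, 18, 27, 40, 60, 90, 135, 200)) {
      d <- pos[(1 + s):n, ] - pos[1:(n - s), ]
      counts[s] <- counts[s] + sum(rowSums(d^2) < rc^2)
      tries[s] <- tries[s] + (n - s)
    }
  }
  ss <- which(tries > 0)
  ps <- data.frame(s = ss, p = counts[ss] / tries[ss])
  fit <- fit_scaling(ps, c(8, 200))
  expect_equal(fit$alpha, -1.5, tolerance = 0.15)
})

test_that("degenerate P(s) is rejected with a diagnostic", {
  tr <- rod_trajectory(100)
  ps <- contact_probability(tr, threshold_nm = 5 * 30, max_sep = 50)
  # rod: a step function (p = 1 up to s = 5, 0 beyond)
  expect_true(all(ps$p[1:5] == 1))
  expect_true(all(ps$p[6:50] == 0))
  expect_error(fit_scaling(ps, c(1, 5)), "degenerate")
  expect_error(fit_scaling(ps, c(10, 50)), "degenerate")
})

test_that("janus profiles: uniform, two-domain and mirror maps", {
  # uniform map -> difference ~ 0 away from the edges
  u <- as_contact_map(matrix(1, 40, 40) + diag(5, 40))
  jp <- janus_profiles(u, window = 5, smooth = 1)
  interior <- 10:30
  expect_true(all(abs(jp$difference[interior]) < 1e-10))
  # two-domain block map: difference negative then positive inside blocks,
  # crossing zero at the junction
  m <- block_contact_map(40, 20)
  jp2 <- janus_profiles(m, window = 8, smooth = 1)
  expect_lt(jp2$difference[18], 0)
  expect_gt(jp2$difference[22], 0)
  # mirror image map -> antisymmetric difference
  rev_counts <- m$counts[40:1, 40:1]
  jpr <- janus_profiles(as_contact_map(rev_counts), window = 8, smooth = 1)
  expect_equal(jpr$difference, -rev(jp2$difference), tolerance = 1e-9)
})

test_that("two-block maps yield exactly one boundary at the junction", {
  for (bpos in c(12, 20, 27)) {
    m <- block_contact_map(40, bpos)
    bs <- find_boundaries(m, "difference-zero-crossing", window = 8)
    expect_equal(nrow(bs), 1)
    expect_lte(abs(bs$bin - bpos), 1)
    bi <- find_boundaries(m, "insulation-peak", window = 8)
    expect_true(any(abs(bi$bin - bpos) <= 1))
  }
  # positions scale with bin size
  m2 <- block_contact_map(40, 20, bin_beads = 40)
  bs2 <- find_boundaries(m2, window = 8)
  expect_equal(bs2$position, bs2$bin * 40)
})

test_that("single-domain maps have no interior boundary", {
  m <- block_contact_map(40, integer(0))
  bs <- find_boundaries(m, window = 8)
  expect_equal(nrow(bs), 0)
})

test_that("boundaries on a reversed map are mirror images", {
  m <- block_contact_map(60, c(20, 45))
  bs <- find_boundaries(m, window = 8)
  mr <- as_contact_map(m$counts[60:1, 60:1])
  bsr <- find_boundaries(mr, window = 8)
  expect_equal(sort(60 - bsr$bin), sort(bs$bin), tolerance = 1)
})

test_that("boundary concordance: identity, disjoint, 3-of-4, and the null", {
  a <- c(1.0e6, 5.0e6, 9.0e6, 13.0e6)
  expect_equal(boundary_concordance(a, a, 1e5)$fraction_recovered, 1)
  expect_equal(boundary_concordance(a, a + 5e5, 1e5)$fraction_recovered, 0)
  q <- c(1.05e6, 5.08e6, 9.02e6, 14.0e6)
  res <- boundary_concordance(q, a, 1e5, n_null = 200, seed = 4)
  expect_equal(res$fraction_recovered, 0.75)
  expect_equal(res$n_matched, 3L)
  expect_lt(res$null_mean, 0.5)
  # greedy matching is one-to-one: two queries cannot claim one reference
  res2 <- boundary_concordance(c(1.01e6, 1.02e6), a, 1e5)
  expect_equal(res2$n_matched, 1L)
})

test_that("averaged homogeneous-fiber maps show no reproducible boundary", {
  # single stochastic runs show pyramids; the 20-run average does not.
  maps <- lapply(1:20, function(s) pyramid_map(50, 10, 4, seed = s))
  avg <- as_contact_map(Reduce(`+`, maps) / 20)
  single <- as_contact_map(maps[[1]])
  ref <- find_boundaries(single, window = 6)   # fixed reference boundaries
  expect_gt(nrow(ref), 0)
  found_avg <- find_boundaries(avg, window = 6)
  res <- boundary_concordance(found_avg$bin, ref$bin, tolerance = 1,
                              span = c(1, 50), n_null = 300, seed = 7)
  # recovered fraction indistinguishable from randomly placed boundaries
  expect_lte(res$fraction_recovered,
             res$null_mean + 3 * max(res$null_sd, 0.05))
})
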