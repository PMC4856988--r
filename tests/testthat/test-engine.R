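# Langevin engine: initialization, integration, neighbor search, protocol.

canon_pairs <- function(p) {
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  dimnames(p) <- NULL
  p
}

test_that("initial conformation is a relaxed self-avoiding walk", {
  f <- toy_fiber(1000, "regular", every = 20)
  fs <- factor_species("red", 50, c(pink = 8, blue = 4))
  sys <- bead_system(f, fs, box_edge = 58.5)
  st <- initialize_conformation(sys, seed = 7)
  pos <- unwrapped_positions(st)
  bl <- sqrt(rowSums((pos[2:1000, ] - pos[1:999, ])^2))
  expect_gt(mean(bl), 0.9)
  expect_lt(mean(bl), 1.1)
  # no steric overlaps below 0.8 sigma after relaxation
  nb <- neighbor_search(st, cutoff = 0.8, strict = TRUE)
  expect_equal(nrow(nb$pairs), 0)
  # wrapped coordinates inside the box
  expect_true(all(st$positions >= 0 & st$positions < sys$box_edge))
})

test_that("initialization is deterministic under the seed", {
  sys <- tiny_system()
  s1 <- initialize_conformation(sys, seed = 3)
  s2 <- initialize_conformation(sys, seed = 3)
  expect_identical(s1$positions, s2$positions)
  s3 <- initialize_conformation(sys, seed = 4)
  expect_false(identical(s1$positions, s3$positions))
})

test_that("many-fiber systems keep per-fiber connectivity", {
  fibers <- replicate(8, toy_fiber(500, "regular", every = 20),
                      simplify = FALSE)
  sys <- bead_system(fibers, list(), box_edge = 93)
  st <- initialize_conformation(sys, seed = 1, relax_steps = 0)
  pos <- unwrapped_positions(st)
  expect_equal(nrow(pos), 4000)
  expect_true(all(st$positions >= 0 & st$positions < sys$box_edge))
  for (fi in 1:8) {
    idx <- which(sys$fiber_id == fi)
    bl <- sqrt(rowSums(diff(pos[idx, ])^2))
    expect_true(all(bl > 0.5 & bl < 1.6))   # bonded chain, not scrambled
  }
})

test_that("free particles diffuse with MSD = 6 D t", {
  fs <- factor_species("red", 1000, c(pink = 0), activation_time = 0)
  sys <- bead_system(list(), fs, box_edge = 80)
  st <- initialize_conformation(sys, seed = 2, relax_steps = 0)
  tr <- run_protocol(sys, duration = 100, dt = 0.01, sample_every = 100,
                     seed = 11, state = st)
  d <- t(tr$positions[, , 2]) - t(tr$positions[, , 1])
  msd <- mean(rowSums(d^2))
  expect_equal(msd / (6 * 100), 1, tolerance = 0.05)
})

test_that("trajectories replay bit-identically under the same seed", {
  sys <- tiny_system(n_beads = 60, n_factors = 5, box = 15, activation = 10)
  t1 <- run_protocol(sys, duration = 100, sample_every = 20, seed = 9)
  t2 <- run_protocol(sys, duration = 100, sample_every = 20, seed = 9)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$times, t2$times)
})

test_that("neighbor search equals the brute-force oracle", {
  set.seed(31)
  box <- 12
  pos <- matrix(runif(500 * 3, 0, box), ncol = 3)
  for (cutoff in c(1.5, 1.8, 5.0)) {
    got <- canon_pairs(neighbor_search(pos, cutoff, box)$pairs)
    want <- canon_pairs(brute_pairs(pos, box, cutoff))
    expect_equal(got, want)
  }
})

test_that("neighbor search handles the periodic boundary and edge cases", {
  box <- 20
  pos <- rbind(c(0.5, 5, 5), c(19.5, 5, 5))   # distance 1 across the seam
  nb <- neighbor_search(pos, 1.2, box)
  expect_equal(nrow(nb$pairs), 1)
  expect_equal(nb$dist, 1, tolerance = 1e-12)
  # empty system
  empty <- neighbor_search(matrix(0, 0, 3), 1.5, box)
  expect_equal(nrow(empty$pairs), 0)
  # cutoff beyond half the box is invalid geometry
  expect_error(neighbor_search(pos, 11, box), "half the box")
})

test_that("zero-temperature relaxation is monotone and finds the bond minimum", {
  # two cognate particles inside the attraction well: energy decreases
  f <- fiber_spec(2, "pink")
  fs <- factor_species("red", 1, c(pink = 8), activation_time = 0)
  sys <- bead_system(f, fs, box_edge = 20)
  pos <- rbind(c(5, 5, 5), c(6, 5, 5), c(5.5, 6.4, 5))
  e <- numeric(30)
  for (k in seq_len(30)) {
    res <- relax_state(sys, pos, n_steps = 1, step_size = 5e-4)
    e[k] <- res$energy
    pos <- res$pos
  }
  expect_true(all(diff(e) <= 1e-10))

  # isolated bonded dimer relaxes to the FENE+WCA force balance
  f2 <- fiber_spec(2, "blue")
  sys2 <- bead_system(f2, list(), box_edge = 20)
  p2 <- rbind(c(5, 5, 5), c(6.3, 5, 5))
  res <- relax_state(sys2, p2, n_steps = 4000, step_size = 1e-3)
  expect_lt(max(abs(res$forces)), 1e-6)
  r_fin <- sqrt(sum((res$pos[2, ] - res$pos[1, ])^2))
  # independent 1-D root of dU/dr for FENE + WCA
  ff <- force_field()
  dU <- function(r) fene_force(r, ff) +
    ifelse(r < 2^(1 / 6), -24 * (2 * r^-13 - r^-7), 0)
  r_star <- uniroot(dU, c(0.8, 1.1), tol = 1e-12)$root
  expect_equal(r_fin, r_star, tolerance = 1e-6)
})

test_that("overstretched bonds abort with a diagnostic", {
  f <- fiber_spec(2, "blue")
  sys <- bead_system(f, list(), box_edge = 20)
  pos <- rbind(c(5, 5, 5), c(6.7, 5, 5))   # beyond R0 = 1.6
  expect_error(system_forces(sys, pos), "exploded bond")
})

test_that("run protocol bookkeeping: snapshot counts and times", {
  sys <- tiny_system(n_beads = 100, n_factors = 5, box = 20,
                     activation = 1000)
  tr <- run_protocol(sys, duration = 5000, sample_every = 500, seed = 1)
  expect_length(tr$times, 11)          # t = 0, 500, ..., 5000
  expect_true(all(diff(tr$times) > 0))
  expect_equal(diff(tr$times), rep(500, 10))
  expect_error(
    run_protocol(sys, duration = 100, seed = 1,
                 schedule = data.frame(time = -5, species = "red",
                                       bead_color = "pink", eps = 2)),
    "before time 0")
})

test_that("scheduled affinity switching lets a second species take over", {
  f <- toy_fiber(100, "regular", every = 10, color = "yellow")
  red <- factor_species("red", 6, c(yellow = 7), activation_time = 0)
  green <- factor_species("green", 6, c(yellow = 0), activation_time = 0)
  sys <- bead_system(f, list(red, green), box_edge = 14)
  sched <- data.frame(time = 500, species = "green", bead_color = "yellow",
                      eps = 12)
  tr <- run_protocol(sys, duration = 2000, sample_every = 200, seed = 5,
                     schedule = sched)
  st <- snapshot_state(tr)
  # green factors are bound to yellow beads at the end
  greens <- which(sys$species == 2)
  yellows <- which(binding_beads(sys, "red"))
  nb <- neighbor_search(st, cutoff = 1.8 * 1.0, strict = FALSE)
  bound_green <- intersect(unique(c(nb$pairs)), greens)
  touching <- vapply(bound_green, function(g) {
    rows <- nb$pairs[, 1] == g | nb$pairs[, 2] == g
    any(c(nb$pairs[rows, ]) %in% yellows)
  }, logical(1))
  expect_gt(sum(touching), 0)
})

test_that("bivalent bridging is emergent: factors contact several cognate beads", {
  sys <- tiny_system(n_beads = 100, n_factors = 10, box = 12,
                     strong = 10, weak = 4, every = 10, activation = 0)
  tr <- run_protocol(sys, duration = 2000, sample_every = 500, seed = 6)
  st <- snapshot_state(tr)
  pinks <- which(binding_beads(sys, high_only = TRUE))
  facs <- which(sys$species > 0)
  nb <- neighbor_search(st, cutoff = 1.8)
  deg <- vapply(facs, function(fc) {
    rows <- nb$pairs[, 1] == fc | nb$pairs[, 2] == fc
    sum(setdiff(c(nb$pairs[rows, ]), fc) %in% pinks)
  }, numeric(1))
  expect_gt(max(deg), 1)   # at least one factor bridges >= 2 cognate beads
})
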