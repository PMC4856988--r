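# Cluster statistics, rosettograms, f_d, radius of gyration.

# system with beads placed by hand: positions given in sigma; a zero-count
# species defines which beads are high-affinity
hand_system <- function(n_beads, box = 120, every = 1) {
  f <- toy_fiber(n_beads, "regular", every = every)
  fs <- factor_species("red", 0, c(pink = 8, blue = 4), activation_time = 0)
  bead_system(f, fs, box_edge = box)
}

state_from <- function(pos, box) {
  structure(list(time = 0, positions = pos - floor(pos / box) * box,
                 images = floor(pos / box), velocities = NULL,
                 box_edge = box), class = "bd_state")
}

test_that("single linkage: pairs, transitive chains, strict cutoff", {
  sys <- hand_system(7, box = 120, every = 2)   # beads 3,5,7 pink (0-based 2,4,6)
  # beads 1,2 at 80 nm (= 8/3 sigma); chain of 5 beads spaced 80 nm
  s <- 80 / 30
  pos <- rbind(c(10, 10, 10), c(10 + s, 10, 10),
               c(50, 50, 50), c(50 + s, 50, 50), c(50 + 2 * s, 50, 50),
               c(50 + 3 * s, 50, 50), c(50 + 4 * s, 50, 50))
  st <- state_from(pos, 120)
  cs <- find_clusters(st, sys, participants = 1:2, cutoff_nm = 90)
  expect_length(cs$members, 1)
  expect_equal(cs$members[[1]], 1:2)
  # chain: ends are 320 nm apart but single linkage joins all five
  cs2 <- find_clusters(st, sys, participants = 3:7, cutoff_nm = 90)
  expect_length(cs2$members, 1)
  expect_equal(sort(cs2$members[[1]]), 3:7)
  # exactly at the cutoff is NOT in one cluster (strict <)
  pos3 <- rbind(c(10, 10, 10), c(13, 10, 10))
  cs3 <- find_clusters(state_from(pos3, 120), sys, participants = 1:2,
                       cutoff_nm = 90)
  expect_length(cs3$members, 0)
})

test_that("clustering equals the brute-force union-find oracle", {
  set.seed(77)
  box <- 30
  for (rep in 1:3) {
    n <- 120
    pos <- matrix(runif(n * 3, 0, box), ncol = 3)
    sys <- hand_system(n, box = box)
    st <- state_from(pos, box)
    for (cutoff_sigma in c(1.5, 3)) {
      cs <- find_clusters(st, sys, participants = seq_len(n),
                          cutoff_nm = cutoff_sigma * 30)
      lab <- brute_clusters(pos, box, cutoff_sigma)
      sizes_oracle <- sort(as.integer(table(lab)[table(lab) >= 2]))
      expect_equal(sort(lengths(cs$members)), sizes_oracle)
      # same partitions, not just sizes
      for (m in cs$members)
        expect_length(unique(lab[m]), 1)
    }
  }
})

test_that("dilute particles are mostly singletons", {
  set.seed(12)
  sys <- hand_system(100, box = 100)
  frac_single <- replicate(5, {
    pos <- matrix(runif(300, 0, 100), ncol = 3)
    cs <- find_clusters(state_from(pos, 100), sys,
                        participants = 1:100, cutoff_nm = 90)
    1 - sum(lengths(cs$members)) / 100
  })
  expect_gte(mean(frac_single), 0.95)
})

test_that("purity summaries", {
  cs <- structure(list(
    members = list(1:5, 6:10),
    colors = list(rep("red", 5), c(rep("red", 4), "green")),
    purity = c(1, 0.8)), class = "cluster_set")
  # recompute purity from colors as the summary does
  expect_equal(cs$purity[1], 1)
  expect_equal(cs$purity[2], 0.8)
  ps <- cluster_purity(cs)
  expect_equal(ps$fraction_pure, 0.5)
  expect_equal(ps$fraction_ge80, 0.5)   # purity > 0.8 strictly
})

test_that("purity and f_d are invariant to relabeling and translation", {
  sys <- tiny_system(n_beads = 100, n_factors = 10, box = 15,
                     strong = 10, weak = 4, every = 10, activation = 0)
  tr <- run_protocol(sys, duration = 1500, sample_every = 500, seed = 13)
  st <- snapshot_state(tr)
  cs <- find_clusters(st, sys, "high_affinity_beads", 90)
  fd1 <- disorganized_fraction(cs, sys)
  # translate the whole box
  st2 <- st
  st2$positions <- (st$positions + 7.3) %% sys$box_edge
  cs2 <- find_clusters(st2, sys, "high_affinity_beads", 90)
  fd2 <- disorganized_fraction(cs2, sys)
  expect_equal(fd1, fd2)
  expect_equal(sort(lengths(cs$members)), sort(lengths(cs2$members)))
})

test_that("f_d: trivial limits and exact complement of neighbor sharing", {
  sys <- hand_system(100, box = 120, every = 10)   # 9 pink beads
  hi <- which(binding_beads(sys, high_only = TRUE))
  # all consecutive high-affinity beads co-clustered -> f_d = 0
  cs_all <- structure(list(members = list(hi)), class = "cluster_set")
  expect_equal(disorganized_fraction(cs_all, sys), 0)
  # nothing clustered -> f_d = 1
  cs_none <- structure(list(members = list()), class = "cluster_set")
  expect_equal(disorganized_fraction(cs_none, sys), 1)
  # mixed case: f_d + sharing fraction = 1 exactly
  cs_mix <- structure(list(members = list(hi[1:3], hi[c(5, 7)])),
                      class = "cluster_set")
  fd <- disorganized_fraction(cs_mix, sys)
  sharing <- 3 / length(hi)  # only the first three share with a fiber neighbor
  expect_equal(fd, 1 - sharing)
})

test_that("rosettogram: hand-built incidence and the perfect rosette", {
  sys <- hand_system(300, box = 150, every = 20)   # pink at 0-based 20,40,...
  hi <- which(binding_beads(sys, high_only = TRUE))
  expect_equal(hi, seq(21, 281, by = 20))
  expect_length(hi, 14)
  # one cluster containing all 14 high-affinity beads: a 14-petal rosette
  cs <- structure(list(members = list(hi)), class = "cluster_set")
  rg <- rosettogram(cs, sys)
  expect_equal(dim(rg$incidence), c(1L, 14L))
  expect_true(all(rg$incidence == 1))
  expect_equal(rg$f_d, 0)
  # hand-built two-cluster incidence
  cs2 <- structure(list(members = list(hi[1:4], hi[9:10])),
                   class = "cluster_set")
  rg2 <- rosettogram(cs2, sys)
  want <- matrix(0L, 2, 14)
  want[1, 1:4] <- 1L
  want[2, 9:10] <- 1L
  expect_equal(unname(rg2$incidence), want)
  # all binding beads singletons -> empty rosettogram
  rg3 <- rosettogram(structure(list(members = list()),
                               class = "cluster_set"), sys)
  expect_equal(nrow(rg3$incidence), 0)
  expect_equal(rg3$f_d, 1)
})

test_that("radius of gyration: closed forms and steady-state summary", {
  sys <- hand_system(10, box = 120)
  # all beads at one point
  pos0 <- matrix(5, 10, 3)
  tr <- list(times = c(0, 1),
             positions = array(rep(t(pos0), 2), dim = c(3, 10, 2)),
             system = sys)
  class(tr) <- "bd_trajectory"
  rg <- radius_of_gyration(tr)
  expect_equal(rg$rg, c(0, 0))
  # straight rod of N beads at unit spacing
  N <- 50
  rod <- cbind(seq_len(N), 0, 0)
  tr2 <- list(times = 0, positions = array(t(rod), dim = c(3, N, 1)),
              system = hand_system(N, box = 200))
  class(tr2) <- "bd_trajectory"
  rg2 <- radius_of_gyration(tr2, steady_window = 1)
  expect_equal(rg2$rg, sqrt((N^2 - 1) / 12), tolerance = 1e-12)
})
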