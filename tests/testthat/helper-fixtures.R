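# Shared fixtures: tiny systems, synthetic contact maps, brute-force oracles.

# a small single-fiber system with one factor species
tiny_system <- function(n_beads = 100, n_factors = 5, box = 20,
                        strong = 8, weak = 4, every = 20,
                        activation = 0, valence = Inf) {
  f <- toy_fiber(n_beads, "regular", every = every)
  fs <- factor_species("red", n_factors, c(pink = strong, blue = weak),
                       activation_time = activation, valence = valence)
  bead_system(f, fs, box_edge = box)
}

# brute-force O(N^2) minimum-image pair search (vectorized all-pairs)
brute_dist_matrix <- function(pos, box) {
  n <- nrow(pos)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(pos[, k], pos[, k], "-")
    dk <- dk - box * round(dk / box)
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

brute_pairs <- function(pos, box, cutoff, strict = FALSE) {
  d <- brute_dist_matrix(pos, box)
  sel <- if (strict) d < cutoff else d <= cutoff
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  which(sel, arr.ind = TRUE)[, c(1, 2), drop = FALSE]
}

# brute-force union-find clustering oracle
brute_clusters <- function(pos, box, cutoff) {
  n <- nrow(pos)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) < cutoff && lab[i] != lab[j]) {
        m <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# synthetic two-block (or multi-block) contact map: strong within-block
# counts, weak background
block_contact_map <- function(n_bins, boundaries_at, high = 60, low = 2,
                              bin_beads = 1) {
  M <- matrix(low, n_bins, n_bins)
  edges <- c(0, boundaries_at, n_bins)
  for (b in seq_len(length(edges) - 1)) {
    idx <- (edges[b] + 1):edges[b + 1]
    M[idx, idx] <- high
  }
  # local decay off the diagonal so the map looks Hi-C-like
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins))
    M[i, j] <- M[i, j] * exp(-abs(i - j) / n_bins)
  M <- (M + t(M)) / 2
  diag(M) <- max(M) * 2
  as_contact_map(M, bin_beads = bin_beads)
}

# single-run-style map with stochastic pyramids (for the averaging null):
# domains of ~domain_bins placed at random positions along the diagonal
pyramid_map <- function(n_bins, domain_bins = 10, n_domains = 5, seed = 1,
                        high = 50, low = 2) {
  set.seed(seed)
  M <- matrix(low, n_bins, n_bins)
  starts <- sort(sample.int(n_bins - domain_bins, n_domains))
  for (s in starts) {
    idx <- s:(s + domain_bins - 1)
    M[idx, idx] <- M[idx, idx] + high
  }
  diag(M) <- max(M) * 2
  M
}
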