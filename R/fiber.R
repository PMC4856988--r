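#' Chromatin fiber specification
#'
#' A fiber is a linear bead-and-spring polymer.  Each bead carries a set of
#' color labels (a bead may carry several colors, e.g. pink and gray beads
#' that bind both transcription factors and heterochromatin proteins), an
#' optional genomic span, and the fiber may carry permanent loop bonds
#' between anchor beads in addition to the backbone.
#'
#' @param n_beads number of beads.
#' @param colors either a character vector (one color per bead) or a list of
#'   character vectors (color sets).  Default all `"blue"` (non-binding).
#' @param persistence_length target persistence length in bead diameters;
#'   converted to the bending modulus with the exact discrete-chain relation
#'   (see [bend_stiffness_for_persistence()]).
#' @param loops integer matrix with two columns of 1-based anchor bead
#'   indices: permanent loop bonds (FENE, identical to backbone bonds).
#' @param genomic optional list `(chrom, start_bp, bead_bp)` mapping bead i
#'   to the 0-based half-open interval
#'   `[start_bp + (i-1)*bead_bp, start_bp + i*bead_bp)`.
#' @param name optional label.
#' @return an object of class `fiber_spec`.
#' @export
fiber_spec <- function(n_beads, colors = "blue", persistence_length = 3,
                       loops = NULL, genomic = NULL, name = "fiber") {
  stopifnot(n_beads >= 2)
  if (!is.list(colors)) {
    colors <- if (length(colors) == 1) rep(colors, n_beads) else colors
    stopifnot(length(colors) == n_beads)
    colors <- as.list(colors)
  }
  stopifnot(length(colors) == n_beads)
  fib <- structure(list(n_beads = as.integer(n_beads), colors = colors,
                        persistence_length = persistence_length,
                        loops = NULL, genomic = genomic, name = name),
                   class = "fiber_spec")
  if (!is.null(loops)) fib <- apply_permanent_loops(fib, loops)
  fib
}

#' @export
print.fiber_spec <- function(x, ...) {
  tab <- sort(table(unlist(x$colors)), decreasing = TRUE)
  cat(sprintf("fiber '%s': %d beads, lp = %.3g sigma, %d permanent loop bond(s)\n",
              x$name, x$n_beads, x$persistence_length,
              if (is.null(x$loops)) 0L else nrow(x$loops)))
  cat("  colors:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

fiber_color_table <- function(fiber) {
  sort(unique(unlist(fiber$colors)))
}

#' Toy fibers with the standard coloring patterns
#'
#' Generates the binding-site layouts used throughout the toy-model studies:
#' \describe{
#'   \item{regular}{one bead in `every` carries `color` (0-based indices
#'     `every, 2*every, ...`; i.e. beads 21, 41, ... in 1-based display for
#'     `every = 20`), the rest are `base_color`.}
#'   \item{poisson}{each bead independently carries `color` with probability
#'     `rate` (default `1/every`), matching the regular pattern's mean linear
#'     density; gap lengths are geometric ("Poisson clumping").}
#'   \item{blocks}{repeating blocks given as a named vector of run lengths,
#'     e.g. `c(light_green = 300, pink = 100)`.}
#'   \item{alternating}{one bead in `every` is a binding bead; binding beads
#'     cycle through `alternating_colors`.}
#'   \item{deserts}{binding blocks of `block_size` beads (`base_color`, with
#'     one bead in `every` recolored `color`) alternate with non-binding
#'     deserts of `desert_size` beads of `desert_color`.}
#'   \item{scatter}{several binding colors scattered randomly: each bead
#'     independently becomes one of `scatter_colors` with probability
#'     `rate` per color (at most one binding color per bead).}
#' }
#'
#' @param n_beads fiber length in beads.
#' @param pattern one of `"regular"`, `"poisson"`, `"blocks"`,
#'   `"alternating"`, `"deserts"`.
#' @param every spacing of binding beads.
#' @param color,base_color binding / background colors.
#' @param rate per-bead binding probability for `"poisson"`.
#' @param blocks named vector of block run lengths for `"blocks"`.
#' @param block_size,desert_size,desert_color desert-pattern geometry.
#' @param alternating_colors colors cycled by `"alternating"`.
#' @param persistence_length passed to [fiber_spec()].
#' @param seed RNG seed for the stochastic patterns (required for
#'   `"poisson"`).
#' @return a [fiber_spec()].
#' @examples
#' f <- toy_fiber(5000, "regular", every = 20)   # Fig-1-style fiber
#' sum(vapply(f$colors, function(cs) "pink" %in% cs, logical(1)))
#' @export
toy_fiber <- function(n_beads,
                      pattern = c("regular", "poisson", "blocks",
                                  "alternating", "deserts", "scatter"),
                      every = 20, color = "pink", base_color = "blue",
                      rate = 1 / every,
                      blocks = c(light_green = 300, pink = 100),
                      block_size = 400, desert_size = 100,
                      desert_color = "gray",
                      alternating_colors = c("pink", "light_green"),
                      scatter_colors = c("pink", "light_green"),
                      persistence_length = 3, seed = NULL) {
  pattern <- match.arg(pattern)
  cols <- rep(base_color, n_beads)
  if (pattern == "regular") {
    if (every <= n_beads - 1) {
      idx0 <- seq.int(every, n_beads - 1, by = every)   # 0-based
      cols[idx0 + 1] <- color
    }
  } else if (pattern == "poisson") {
    if (is.null(seed)) stop("poisson pattern requires a seed")
    cols[with_seed(seed, stats::runif(n_beads)) < rate] <- color
  } else if (pattern == "blocks") {
    stopifnot(!is.null(names(blocks)), all(blocks >= 1))
    runs <- rep(rep(names(blocks), times = blocks),
                length.out = n_beads)
    cols <- runs
  } else if (pattern == "alternating") {
    idx0 <- seq.int(every, n_beads - 1, by = every)
    cols[idx0 + 1] <- rep(alternating_colors,
                          length.out = length(idx0))
  } else if (pattern == "scatter") {
    if (is.null(seed)) stop("scatter pattern requires a seed")
    stopifnot(rate * length(scatter_colors) <= 1)
    u <- with_seed(seed, stats::runif(n_beads))
    idx <- floor(u / rate) + 1
    hit <- idx <= length(scatter_colors)
    cols[hit] <- scatter_colors[idx[hit]]
  } else if (pattern == "deserts") {
    period <- block_size + desert_size
    pos0 <- seq_len(n_beads) - 1           # 0-based
    inblock <- (pos0 %% period) < block_size
    cols[!inblock] <- desert_color
    local0 <- pos0 %% period
    pink <- inblock & local0 %% every == 0 & local0 > 0
    cols[pink] <- color
  }
  fiber_spec(n_beads, cols, persistence_length = persistence_length,
             name = paste0("toy_", pattern))
}

#' Add permanent loop bonds to a fiber
#'
#' Anchor pairs are joined by FENE bonds identical to backbone bonds, forcing
#' the fiber into permanent loops (e.g. 324-bead loops separated by 300
#' unlooped beads).  Pairs are deduplicated (unordered), pairs duplicating a
#' backbone bond or adjacent on the backbone are rejected as degenerate.
#'
#' @param fiber a [fiber_spec()].
#' @param anchor_pairs 2-column matrix of 1-based bead indices (or a length-2
#'   vector).  An empty matrix / `NULL` leaves the fiber unchanged.
#' @return the fiber with loop bonds added (idempotent).
#' @export
apply_permanent_loops <- function(fiber, anchor_pairs) {
  if (is.null(anchor_pairs) || NROW(anchor_pairs) == 0) return(fiber)
  ap <- matrix(as.integer(anchor_pairs), ncol = 2)
  stopifnot(all(ap >= 1), all(ap <= fiber$n_beads))
  if (any(ap[, 1] == ap[, 2])) stop("loop anchor pair with identical beads")
  ap <- t(apply(ap, 1, sort))
  if (any(ap[, 2] - ap[, 1] == 1))
    stop("anchor pair adjacent on the backbone (degenerate loop)")
  all_pairs <- rbind(fiber$loops, ap)
  fiber$loops <- unique(all_pairs)
  fiber
}

#' Regularly spaced loop anchor pairs
#'
#' Computes the anchor pairs that pre-organize a fiber into loops of
#' `loop_beads` beads separated by `gap_beads` unlooped beads, with
#' `end_beads` unlooped beads at each end (as many loops as fit).
#'
#' @param n_beads fiber length.
#' @param loop_beads beads per loop (anchors included).
#' @param gap_beads unlooped beads between loops.
#' @param end_beads unlooped beads at each end.
#' @return 2-column matrix of 1-based anchor indices.
#' @export
regular_loop_anchors <- function(n_beads, loop_beads = 324, gap_beads = 300,
                                 end_beads = 150) {
  start <- end_beads + 1
  out <- NULL
  while (start + loop_beads - 1 <= n_beads - end_beads) {
    out <- rbind(out, c(start, start + loop_beads - 1))
    start <- start + loop_beads + gap_beads
  }
  out
}

# evaluate expr under a fixed seed without disturbing the global RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
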