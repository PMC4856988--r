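#' Load a run recipe
#'
#' A recipe is a YAML file that fully determines a simulation (given a
#' seed): unit system, box, fibers (coloring pattern or synthetic
#' annotation), factor species with affinities in kBT, protocol times and
#' analysis thresholds.  The package ships recipes for the standard
#' toy-model and chromosome-style setups (`fig1a`, `fig1b`, `fig2a`,
#' `fig2c`, `fig3a`, `fig3b`, `fig3c`, `fig3d`, `chr_synthetic`); `file`
#' may be one of those names or a path.  Unknown keys are rejected.
#'
#' @param file recipe name or YAML path.
#' @return a `run_recipe` list.
#' @export
load_recipe <- function(file) {
  path <- if (file.exists(file)) file
          else system.file("recipes", paste0(file, ".yaml"),
                           package = "chromobridge")
  if (!nzchar(path) || !file.exists(path))
    stop("recipe not found: ", file)
  rec <- yaml::read_yaml(path)
  known <- c("name", "description", "units", "box_edge_nm", "fibers",
             "factors", "duration", "dt", "sample_every", "analysis",
             "schedule", "scale")
  unknown <- setdiff(names(rec), known)
  if (length(unknown))
    stop("unknown recipe key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(dt = 0.01, sample_every = 1000, scale = 1,
                   units = list(sigma_nm = 30, kbp_per_bead = 3,
                                viscosity_Pa_s = 0.01, temperature_K = 300),
                   analysis = list(contact_threshold_nm = 150,
                                   cluster_cutoff_nm = 90, bin_beads = 40))
  for (k in names(defaults)) {
    if (is.null(rec[[k]])) rec[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      for (k2 in names(defaults[[k]]))
        if (is.null(rec[[k]][[k2]])) rec[[k]][[k2]] <- defaults[[k]][[k2]]
  }
  stopifnot(!is.null(rec$name), !is.null(rec$box_edge_nm),
            !is.null(rec$fibers), !is.null(rec$duration))
  structure(rec, class = "run_recipe")
}

#' @export
print.run_recipe <- function(x, ...) {
  cat(sprintf("recipe '%s' (scale %.3g): box %.4g nm, duration %.4g tau\n",
              x$name, x$scale, x$box_edge_nm, x$duration))
  for (f in x$fibers)
    cat(sprintf("  fiber: %d beads x%d, pattern %s\n",
                f$n_beads %||% -1L, f$replicates %||% 1L,
                f$pattern %||% "?"))
  for (fs in x$factors %||% list())
    cat(sprintf("  factors %s: n=%d, affinity %s\n", fs$color, fs$count,
                paste(sprintf("%s=%.3g", names(fs$affinity),
                              unlist(fs$affinity)), collapse = " ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale a recipe down (or keep it at full size)
#'
#' Bead and factor counts are scaled together and the box edge is scaled as
#' the cube root of the realized bead ratio, so all volume fractions (and
#' hence concentrations) are preserved; thresholds, sigma and durations are
#' unchanged.  Fibers with `replicates` have the replicate count scaled
#' first.  Scaling below 100 total beads is refused.
#'
#' @param recipe a `run_recipe`.
#' @param factor scale in (0, 1].
#' @return the scaled `run_recipe`.
#' @export
scale_recipe <- function(recipe, factor) {
  stopifnot(factor > 0, factor <= 1)
  if (factor == 1) return(recipe)
  tot0 <- total_recipe_beads(recipe)
  for (i in seq_along(recipe$fibers)) {
    f <- recipe$fibers[[i]]
    rep0 <- f$replicates %||% 1L
    rep1 <- max(1L, as.integer(round(rep0 * factor)))
    resid <- factor * rep0 / rep1
    if (identical(f$pattern, "annotation")) {
      f$region_bp <- round(f$region_bp * resid / f$bead_bp) * f$bead_bp
    } else {
      f$n_beads <- as.integer(round(f$n_beads * resid))
    }
    f$replicates <- rep1
    recipe$fibers[[i]] <- f
  }
  tot1 <- total_recipe_beads(recipe)
  if (tot1 < 100)
    stop("scaled system has ", tot1, " beads; minimum viable is 100")
  ratio <- tot1 / tot0
  for (i in seq_along(recipe$factors))
    recipe$factors[[i]]$count <-
      as.integer(round(recipe$factors[[i]]$count * ratio))
  recipe$box_edge_nm <- recipe$box_edge_nm * ratio^(1 / 3)
  recipe$scale <- recipe$scale * factor
  recipe
}

total_recipe_beads <- function(recipe) {
  sum(vapply(recipe$fibers, function(f) {
    n <- if (identical(f$pattern, "annotation")) f$region_bp %/% f$bead_bp
         else f$n_beads
    n * (f$replicates %||% 1L)
  }, numeric(1)))
}

# build fiber_spec list + unit system from a recipe
recipe_fibers <- function(recipe, seed) {
  units <- do.call(unit_system, recipe$units)
  out <- list()
  for (f in recipe$fibers) {
    reps <- f$replicates %||% 1L
    for (r in seq_len(reps)) {
      fib <- switch(f$pattern,
        regular = ,
        poisson = ,
        blocks = ,
        alternating = ,
        scatter = ,
        deserts = {
          args <- f[setdiff(names(f), c("pattern", "replicates", "loops",
                                        "uniform_color"))]
          args$pattern <- f$pattern
          if (f$pattern %in% c("poisson", "scatter"))
            args$seed <- seed + 1000 * r
          if (!is.null(f$blocks)) args$blocks <- unlist(f$blocks)
          if (!is.null(f$scatter_colors))
            args$scatter_colors <- unlist(f$scatter_colors)
          do.call(toy_fiber, args)
        },
        uniform = fiber_spec(f$n_beads, f$uniform_color %||% "pink",
                             persistence_length =
                               f$persistence_length %||% 3),
        annotation = {
          ann <- synthesize_annotation(
            region_bp = f$region_bp, bead_bp = f$bead_bp,
            proportions = f$proportions, seed = seed + 1000 * r)
          cfg <- paint_config(bead_bp = f$bead_bp)
          cfg$gc_threshold <- calibrate_gc_threshold(ann$gc, ann$track, cfg)
          painted_fiber(paint_beads(ann$track, ann$gc, cfg))
        },
        stop("unknown fiber pattern: ", f$pattern))
      if (!is.null(f$loops)) {
        anchors <- do.call(regular_loop_anchors,
                           c(list(n_beads = fib$n_beads), f$loops))
        fib <- apply_permanent_loops(fib, anchors)
      }
      out <- c(out, list(fib))
    }
  }
  list(fibers = out, units = units)
}

#' Build the simulation system described by a recipe
#'
#' @param recipe a `run_recipe` (already scaled if desired).
#' @param seed seed used for stochastic fiber patterns and synthetic
#'   annotations.
#' @return a [bead_system()].
#' @export
recipe_system <- function(recipe, seed = 1) {
  rf <- recipe_fibers(recipe, seed)
  factors <- lapply(recipe$factors %||% list(), function(fs)
    factor_species(fs$color, fs$count, unlist(fs$affinity),
                   diameter = fs$diameter %||% 1,
                   activation_time = fs$activation_time %||% 1e4,
                   valence = if (identical(fs$valence, 1L) ||
                                 identical(fs$valence, 1)) 1 else Inf))
  bead_system(rf$fibers, factors,
              box_edge = recipe$box_edge_nm / rf$units$sigma_nm,
              units = rf$units)
}

#' Run a recipe end to end
#'
#' Builds the system, runs the protocol (equilibration with binding off
#' until each species' activation time, then clustering) and returns the
#' trajectory.  `scale` applies [scale_recipe()] first.
#'
#' @param recipe a `run_recipe` or recipe name.
#' @param seed master seed.
#' @param scale scale factor in (0, 1].
#' @param duration optional override of the recipe duration, tau.
#' @return a `bd_trajectory` (the recipe is attached as `$recipe`).
#' @export
run_recipe <- function(recipe, seed = 1, scale = 1, duration = NULL) {
  if (is.character(recipe)) recipe <- load_recipe(recipe)
  if (scale != 1) recipe <- scale_recipe(recipe, scale)
  sys <- recipe_system(recipe, seed)
  schedule <- if (!is.null(recipe$schedule))
    do.call(rbind, lapply(recipe$schedule, as.data.frame)) else NULL
  tr <- run_protocol(sys, duration = duration %||% recipe$duration,
                     dt = recipe$dt, sample_every = recipe$sample_every,
                     seed = seed, schedule = schedule)
  tr$recipe <- recipe
  tr
}

#' Round-trip a recipe to YAML
#' @param recipe a `run_recipe`.
#' @param file output path.
#' @export
write_recipe <- function(recipe, file) {
  yaml::write_yaml(unclass(recipe), file)
}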