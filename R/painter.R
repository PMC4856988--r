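#' Painting configuration
#'
#' Rules mapping chromatin-state annotation and GC content to bead colors:
#' a bead is pink when at least `min_overlap_bp` of it is labeled active
#' promoter / strong enhancer (states 1, 4, 5), light-green when at least
#' `min_overlap_bp` is transcriptional transition / elongation (states 9,
#' 10), gray when its GC fraction is strictly below `gc_threshold` (or,
#' without a GC track, when at least `min_overlap_bp` is heterochromatin
#' state 13), and blue otherwise.  Rules apply independently, so one bead
#' can carry several colors.
#'
#' @param bead_bp bp per bead (1000 or 3000 in the standard mappings).
#' @param active_states,elongation_states,heterochromatin_states state-id
#'   groups.
#' @param min_overlap_bp overlap needed to color a bead (90 bp).
#' @param gc_threshold GC fraction below which a bead is gray, or `NULL` to
#'   use the state-13 rule.
#' @param overlap_mode `"pooled"`: total overlap of all qualifying states
#'   within the bead; `"contiguous"`: a single contiguous qualifying run
#'   must reach `min_overlap_bp` (qualifying intervals merged first).
#' @return a `paint_config` list.
#' @export
paint_config <- function(bead_bp = 1000, active_states = c(1, 4, 5),
                         elongation_states = c(9, 10),
                         heterochromatin_states = 13,
                         min_overlap_bp = 90, gc_threshold = NULL,
                         overlap_mode = c("pooled", "contiguous")) {
  stopifnot(bead_bp >= 1, min_overlap_bp <= bead_bp)
  structure(list(bead_bp = as.integer(bead_bp),
                 active_states = active_states,
                 elongation_states = elongation_states,
                 heterochromatin_states = heterochromatin_states,
                 min_overlap_bp = min_overlap_bp,
                 gc_threshold = gc_threshold,
                 overlap_mode = match.arg(overlap_mode)),
            class = "paint_config")
}

#' Chromatin-state interval track
#'
#' Normalizes a set of (chrom, start, end, state) intervals: 0-based
#' half-open coordinates, sorted, zero-width dropped; overlapping intervals
#' of the same state are merged.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `state`.
#' @return a `state_track` (normalized data.frame).
#' @export
state_track <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(df)))
  df <- df[df$end > df$start, , drop = FALSE]
  if (any(df$start < 0)) stop("negative interval start")
  out <- do.call(rbind, lapply(split(df, list(df$chrom, df$state),
                                     drop = TRUE), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1, g$end))
    data.frame(chrom = g$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), state = g$state[1])
  }))
  out <- out[order(out$chrom, out$start, out$end, out$state), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("state_track", "data.frame"))
}

#' Read a ChromHMM-style BED track
#'
#' Accepts 4+ column BED where the name field is either a plain state
#' integer (`"13"`) or the `"1_Active_Promoter"` dialect.
#'
#' @param file BED path.
#' @return a [state_track()].
#' @export
read_state_track <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("state BED needs at least 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  st <- suppressWarnings(as.integer(sub("_.*$", "", df$name)))
  if (anyNA(st)) stop("could not parse state ids from BED name field")
  state_track(data.frame(chrom = df$chrom, start = df$start, end = df$end,
                         state = st))
}

#' @rdname read_state_track
#' @param track a [state_track()].
#' @export
write_state_track <- function(track, file) {
  utils::write.table(
    data.frame(track$chrom, track$start, track$end, track$state),
    file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Windowed GC content
#'
#' G+C fraction of consecutive bead-sized windows, with N bases excluded
#' from the denominator; all-N windows get `NA` and windows with more than
#' half N are flagged (painted blue rather than gray downstream).
#'
#' @param x a `Biostrings::DNAString`, `DNAStringSet` (first sequence used),
#'   or FASTA file path.
#' @param bead_bp window size, bp.
#' @return a `gc_track`: numeric vector of per-bead GC fractions with
#'   attributes `bead_bp` and `flagged` (logical, > 50% N).
#' @export
gc_fraction_windows <- function(x, bead_bp) {
  if (is.character(x)) x <- Biostrings::readDNAStringSet(x)
  if (inherits(x, "DNAStringSet")) x <- x[[1]]
  stopifnot(inherits(x, "DNAString"))
  n_beads <- length(x) %/% bead_bp
  if (n_beads < 1) stop("sequence shorter than one bead")
  starts <- (seq_len(n_beads) - 1) * bead_bp + 1
  v <- Biostrings::Views(x, start = starts, width = bead_bp)
  freq <- Biostrings::letterFrequency(v, c("G", "C", "N"))
  nn <- freq[, "N"]
  denom <- bead_bp - nn
  gc <- ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / denom, NA_real_)
  structure(gc, bead_bp = as.integer(bead_bp),
            flagged = nn > bead_bp / 2, class = "gc_track")
}

#' @export
print.gc_track <- function(x, ...) {
  cat(sprintf("GC track: %d windows of %d bp, mean GC %.3f, %d flagged (>50%% N)\n",
              length(x), attr(x, "bead_bp"), mean(unclass(x), na.rm = TRUE),
              sum(attr(x, "flagged"))))
  invisible(x)
}

#' Build a GC track from per-bead values
#' @param values numeric GC fractions in `[0, 1]`.
#' @param bead_bp window size metadata.
#' @export
gc_track <- function(values, bead_bp) {
  stopifnot(all(values >= 0 & values <= 1, na.rm = TRUE))
  structure(as.numeric(values), bead_bp = as.integer(bead_bp),
            flagged = rep(FALSE, length(values)), class = "gc_track")
}

# total (or max-contiguous) overlap of a state group with each bead, in bp
state_overlap_per_bead <- function(track, states, chrom, region_start,
                                   n_beads, cfg) {
  sel <- track$chrom == chrom & track$state %in% states
  out <- numeric(n_beads)
  if (!any(sel)) return(out)
  ir <- IRanges::IRanges(track$start[sel] + 1, track$end[sel])
  if (cfg$overlap_mode == "contiguous") ir <- IRanges::reduce(ir)
  beads <- IRanges::IRanges(region_start + (seq_len(n_beads) - 1) * cfg$bead_bp + 1,
                            width = cfg$bead_bp)
  hits <- IRanges::findOverlaps(beads, ir)
  if (!length(hits)) return(out)
  w <- IRanges::width(IRanges::pintersect(
    beads[S4Vectors::queryHits(hits)], ir[S4Vectors::subjectHits(hits)]))
  if (cfg$overlap_mode == "pooled") {
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  } else {
    agg <- tapply(w, S4Vectors::queryHits(hits), max)
  }
  out[as.integer(names(agg))] <- agg
  out
}

#' Paint beads from annotation
#'
#' Applies the coloring rules of [paint_config()] to a genomic region tiled
#' with beads.  Every bead must be fully covered by the state track (any
#' state); an uncovered bead raises a gap error rather than silently
#' becoming blue.
#'
#' @param track a [state_track()].
#' @param gc optional `gc_track` aligned to the bead grid; when supplied,
#'   gray is decided by `gc < gc_threshold` (strict), otherwise by the
#'   state-13 rule.
#' @param cfg a [paint_config()]; `gc_threshold` must be set when `gc` is
#'   given (see [calibrate_gc_threshold()]).
#' @param chrom chromosome to paint (default: the single chromosome in the
#'   track).
#' @param region_start,region_end painted span, bp (0-based half-open;
#'   default: full multiple of `bead_bp` from 0 to the track end).
#' @return a `bead_painting`: list with `colors` (list of per-bead color
#'   sets), `chrom`, `region_start`, `bead_bp`, `n_beads`.
#' @export
paint_beads <- function(track, gc = NULL, cfg = paint_config(),
                        chrom = NULL, region_start = 0, region_end = NULL) {
  if (is.null(chrom)) {
    chrom <- unique(track$chrom)
    if (length(chrom) != 1) stop("track has several chromosomes; give `chrom`")
  }
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (!nrow(tr)) stop("track does not cover chromosome ", chrom)
  if (is.null(region_end))
    region_end <- region_start +
      ((max(tr$end) - region_start) %/% cfg$bead_bp) * cfg$bead_bp
  n_beads <- (region_end - region_start) %/% cfg$bead_bp
  if (n_beads < 1) stop("region shorter than one bead")

  # coverage check: every base of every bead must be covered by some state
  cov_cfg <- cfg
  cov_cfg$overlap_mode <- "pooled"
  cover <- state_overlap_per_bead(tr, unique(tr$state), chrom, region_start,
                                  n_beads, cov_cfg)
  if (any(cover < cfg$bead_bp)) {
    bad <- which(cover < cfg$bead_bp)[1]
    stop(sprintf(
      "annotation gap: bead %d [%d, %d) only covered for %d of %d bp",
      bad, region_start + (bad - 1) * cfg$bead_bp,
      region_start + bad * cfg$bead_bp, cover[bad], cfg$bead_bp))
  }

  pink <- state_overlap_per_bead(tr, cfg$active_states, chrom, region_start,
                                 n_beads, cfg) >= cfg$min_overlap_bp
  lgreen <- state_overlap_per_bead(tr, cfg$elongation_states, chrom,
                                   region_start, n_beads, cfg) >=
    cfg$min_overlap_bp
  if (!is.null(gc)) {
    if (is.null(cfg$gc_threshold))
      stop("gc track given but cfg$gc_threshold is not set")
    if (length(gc) < n_beads) stop("gc track does not cover the region")
    v <- unclass(gc)[seq_len(n_beads)]
    flagged <- attr(gc, "flagged")[seq_len(n_beads)] | is.na(v)
    gray <- !flagged & v < cfg$gc_threshold   # strict: at-threshold not gray
    if (any(flagged))
      message(sum(flagged), " bead(s) with >50% N painted blue")
  } else {
    gray <- state_overlap_per_bead(tr, cfg$heterochromatin_states, chrom,
                                   region_start, n_beads, cfg) >=
      cfg$min_overlap_bp
  }
  colors <- lapply(seq_len(n_beads), function(i) {
    cs <- c(if (pink[i]) "pink", if (lgreen[i]) "light_green",
            if (gray[i]) "gray")
    if (is.null(cs)) "blue" else cs
  })
  structure(list(colors = colors, chrom = chrom,
                 region_start = region_start, bead_bp = cfg$bead_bp,
                 n_beads = n_beads),
            class = "bead_painting")
}

#' @export
print.bead_painting <- function(x, ...) {
  tab <- sort(table(unlist(x$colors)), decreasing = TRUE)
  cat(sprintf("bead painting: %s, %d beads of %d bp from %d\n", x$chrom,
              x$n_beads, x$bead_bp, x$region_start))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Painting to fiber and to TSV
#'
#' `painted_fiber` turns a painting into a [fiber_spec()] (multi-color beads
#' preserved); `write_painting` exports a diffable BED-like TSV
#' (chrom, start, end, comma-separated color set).
#'
#' @param painting a `bead_painting`.
#' @param persistence_length fiber stiffness, sigma.
#' @export
painted_fiber <- function(painting, persistence_length = 3) {
  fiber_spec(painting$n_beads, painting$colors,
             persistence_length = persistence_length,
             genomic = list(chrom = painting$chrom,
                            start_bp = painting$region_start,
                            bead_bp = painting$bead_bp),
             name = paste0(painting$chrom, "_painted"))
}

#' @rdname painted_fiber
#' @param file output path.
#' @export
write_painting <- function(painting, file) {
  df <- data.frame(
    chrom = painting$chrom,
    start = painting$region_start +
      (seq_len(painting$n_beads) - 1) * painting$bead_bp,
    end = painting$region_start +
      seq_len(painting$n_beads) * painting$bead_bp,
    colors = vapply(painting$colors, paste, character(1), collapse = ","))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Calibrate the GC threshold against the state-13 fraction
#'
#' Returns the GC value such that the fraction of beads strictly below it
#' equals the fraction of beads carrying at least `min_overlap_bp` of
#' heterochromatin state 13 (the threshold is a GC quantile).  With all-NA
#' or constant GC the calibration is degenerate and raises an error.
#'
#' @param gc a `gc_track`.
#' @param track a [state_track()] covering the same bead grid.
#' @param cfg a [paint_config()].
#' @param chrom,region_start painted region (as in [paint_beads()]).
#' @return the threshold GC fraction.
#' @export
calibrate_gc_threshold <- function(gc, track, cfg = paint_config(),
                                   chrom = NULL, region_start = 0) {
  if (is.null(chrom)) {
    chrom <- unique(track$chrom)
    if (length(chrom) != 1) stop("track has several chromosomes; give `chrom`")
  }
  v <- unclass(gc)
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 2 || length(unique(v)) < 2)
    stop("degenerate GC track: need at least two distinct values")
  het <- state_overlap_per_bead(track, cfg$heterochromatin_states, chrom,
                                region_start, length(gc), cfg) >=
    cfg$min_overlap_bp
  target <- mean(het)
  k <- round(target * n)
  s <- sort(v)
  if (k <= 0) return(s[1])          # strict '<' => no gray beads
  if (k >= n) return(s[n] + 1e-9)
  s[k + 1]
}

#' Synthesize a chromatin-state annotation with matched statistics
#'
#' Generates a full state partition plus a correlated GC profile over a
#' region, such that painting it at `bead_bp` reproduces the requested
#' per-bead eligible fractions: `active` beads receive at least 90 bp of a
#' state from \{1, 4, 5\}, `elongation` beads at least 90 bp of \{9, 10\},
#' `heterochromatin` beads at least 90 bp of state 13 and a down-shifted GC
#' value.  Remaining bases are filled with the non-qualifying background
#' state 11, so the track has no gaps.  The GC profile is an AR(1) series
#' (lag-1 autocorrelation `gc_autocorr`) around `gc_base`.  Deterministic
#' under `seed`.
#'
#' @param region_bp region length, bp (multiple of `bead_bp`).
#' @param bead_bp bead size, bp.
#' @param proportions list with `active`, `elongation`, `heterochromatin`
#'   per-bead fractions (drawn independently, so beads may qualify for
#'   several colors).
#' @param seed integer seed.
#' @param chrom chromosome label.
#' @param gc_base,gc_sd,gc_autocorr,gc_het_shift GC profile parameters.
#' @param seg_len_bp mean qualifying-interval length, bp (at least 90).
#' @return list with `track` (a [state_track()]) and `gc` (a `gc_track`).
#' @export
synthesize_annotation <- function(region_bp, bead_bp = 1000,
                                  proportions = list(active = 0.04,
                                                     elongation = 0.06,
                                                     heterochromatin = 0.30),
                                  seed = 1, chrom = "chrSim",
                                  gc_base = 0.50, gc_sd = 0.03,
                                  gc_autocorr = 0.8, gc_het_shift = -0.10,
                                  seg_len_bp = 300) {
  stopifnot(region_bp %% bead_bp == 0, seg_len_bp >= 90,
            seg_len_bp <= bead_bp %/% 3)
  p <- proportions
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1))
  n <- region_bp %/% bead_bp
  with_seed(seed, {
    pick <- function(frac) sort(sample.int(n, round(frac * n)))
    act <- pick(p$active)
    elo <- pick(p$elongation)
    het <- pick(p$heterochromatin)
    mk_iv <- function(beads, states, third) {
      if (!length(beads)) return(NULL)
      len <- pmax(90, pmin(bead_bp %/% 3 - 10,
                           round(stats::rexp(length(beads), 1 / seg_len_bp))))
      off <- (beads - 1) * bead_bp + (third - 1) * (bead_bp %/% 3)
      st <- if (length(states) == 1) rep(states, length(beads))
            else sample(states, length(beads), replace = TRUE)
      data.frame(chrom = chrom, start = off, end = off + len, state = st)
    }
    iv <- rbind(mk_iv(act, c(1, 4, 5), 1),
                mk_iv(elo, c(9, 10), 2),
                mk_iv(het, 13, 3))
    # background fill: complement within [0, region_bp)
    occ <- if (is.null(iv)) IRanges::IRanges() else
      IRanges::reduce(IRanges::IRanges(iv$start + 1, iv$end))
    gaps <- IRanges::gaps(occ, start = 1, end = region_bp)
    bg <- data.frame(chrom = chrom, start = IRanges::start(gaps) - 1,
                     end = IRanges::end(gaps), state = 11)
    track <- state_track(rbind(iv, bg))
    # AR(1) GC profile; heterochromatic beads shifted low
    z <- numeric(n)
    z[1] <- stats::rnorm(1)
    for (i in seq_len(n - 1))
      z[i + 1] <- gc_autocorr * z[i] +
        sqrt(1 - gc_autocorr^2) * stats::rnorm(1)
    gcv <- gc_base + gc_sd * z
    gcv[het] <- gcv[het] + gc_het_shift
    gcv <- pmin(0.95, pmax(0.05, gcv))
    list(track = track, gc = gc_track(gcv, bead_bp))
  })
}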