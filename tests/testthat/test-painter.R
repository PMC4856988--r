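# Annotation-to-bead-color pipeline.

simple_track <- function(ivs, chrom = "chr1") {
  state_track(data.frame(chrom = chrom, start = vapply(ivs, `[[`, 0, 1),
                         end = vapply(ivs, `[[`, 0, 2),
                         state = vapply(ivs, `[[`, 0, 3)))
}

# fully covered 3-bead track at 1 kbp: background state 11 everywhere,
# plus extra intervals layered on top
covered_track <- function(extra = list(), n_bp = 3000) {
  base <- list(list(0, n_bp, 11))
  simple_track(c(base, extra))
}

test_that("90 bp rule: pink/light-green coloring with strict threshold", {
  cfg <- paint_config(bead_bp = 1000)
  # 100 bp of state 1 -> pink
  tr <- covered_track(list(list(200, 300, 1)))
  p <- paint_beads(tr, cfg = cfg)
  expect_equal(p$colors[[1]], "pink")
  expect_equal(p$colors[[2]], "blue")
  # 89 bp of state 4 stays blue
  tr89 <- covered_track(list(list(200, 289, 4)))
  expect_equal(paint_beads(tr89, cfg = cfg)$colors[[1]], "blue")
  # exactly 90 bp qualifies
  tr90 <- covered_track(list(list(200, 290, 4)))
  expect_equal(paint_beads(tr90, cfg = cfg)$colors[[1]], "pink")
  # state 9 -> light green; state 13 -> gray (no GC track)
  tr2 <- covered_track(list(list(100, 300, 9), list(1100, 1300, 13)))
  p2 <- paint_beads(tr2, cfg = cfg)
  expect_equal(p2$colors[[1]], "light_green")
  expect_equal(p2$colors[[2]], "gray")
})

test_that("a 3 kbp bead can be light-green and gray at once", {
  cfg <- paint_config(bead_bp = 3000, gc_threshold = 0.484)
  tr <- covered_track(list(list(500, 700, 9)), n_bp = 3000)
  gc <- gc_track(0.40, bead_bp = 3000)
  p <- paint_beads(tr, gc, cfg)
  expect_setequal(p$colors[[1]], c("light_green", "gray"))
})

test_that("interval fragmentation does not change the pooled coloring", {
  cfg <- paint_config(bead_bp = 1000)
  whole <- covered_track(list(list(200, 300, 1)))
  split2 <- covered_track(list(list(200, 250, 1), list(250, 300, 1)))
  expect_identical(paint_beads(whole, cfg = cfg)$colors,
                   paint_beads(split2, cfg = cfg)$colors)
  # pooling across states of one group also counts
  mixed <- covered_track(list(list(200, 250, 1), list(600, 645, 5)))
  expect_equal(paint_beads(mixed, cfg = cfg)$colors[[1]], "pink")
  # contiguous mode requires a single qualifying run
  cfgc <- paint_config(bead_bp = 1000, overlap_mode = "contiguous")
  expect_equal(paint_beads(mixed, cfg = cfgc)$colors[[1]], "blue")
  expect_equal(paint_beads(split2, cfg = cfgc)$colors[[1]], "pink")
})

test_that("annotation gaps raise an error instead of silent blue", {
  tr <- simple_track(list(list(0, 500, 11), list(700, 3000, 11)))
  expect_error(paint_beads(tr, cfg = paint_config(bead_bp = 1000)),
               "gap")
})

test_that("GC windows: trivial sequences and N handling", {
  s <- Biostrings::DNAString(paste0(
    strrep("GC", 500),                       # bead 1: all G/C -> 1.0
    strrep("ACGT", 250),                     # bead 2: balanced -> 0.5
    strrep("A", 500), strrep("N", 500)))     # bead 3: AT + N
  gc <- gc_fraction_windows(s, 1000)
  expect_equal(unclass(gc)[1:2], c(1, 0.5))
  expect_equal(unclass(gc)[3], 0)            # N excluded from denominator
  expect_false(attr(gc, "flagged")[3])       # exactly 50% N not flagged
  s2 <- Biostrings::DNAString(strrep("N", 1000))
  expect_true(is.na(unclass(gc_fraction_windows(s2, 1000))[1]))
})

test_that("GC threshold boundary: a bead exactly at threshold is not gray", {
  cfg <- paint_config(bead_bp = 1000, gc_threshold = 0.418)
  tr <- covered_track(list(), n_bp = 3000)
  gc <- gc_track(c(0.418, 0.4179, 0.50), bead_bp = 1000)
  p <- paint_beads(tr, gc, cfg)
  expect_equal(p$colors[[1]], "blue")    # exactly at threshold: strict <
  expect_equal(p$colors[[2]], "gray")
  expect_equal(p$colors[[3]], "blue")
})

test_that("GC threshold calibration matches the state-13 fraction", {
  set.seed(8)
  n <- 200
  gcv <- sample(seq(0.30, 0.70, length.out = n))   # distinct values
  het_beads <- sort(sample.int(n, 60))             # exactly 30%
  ivs <- lapply(het_beads, function(b)
    list((b - 1) * 1000 + 100, (b - 1) * 1000 + 300, 13))
  tr <- covered_track(ivs, n_bp = n * 1000)
  gc <- gc_track(gcv, 1000)
  thr <- calibrate_gc_threshold(gc, tr, paint_config(bead_bp = 1000))
  expect_equal(mean(gcv < thr), 0.30)
  # no state 13 at all: threshold at/below the minimum, no gray beads
  tr0 <- covered_track(list(), n_bp = n * 1000)
  thr0 <- calibrate_gc_threshold(gc, tr0, paint_config(bead_bp = 1000))
  expect_equal(mean(gcv < thr0), 0)
  expect_error(calibrate_gc_threshold(gc_track(rep(0.5, n), 1000), tr,
                                      paint_config(bead_bp = 1000)),
               "degenerate")
})

test_that("synthetic annotation realizes requested per-bead fractions", {
  ann <- synthesize_annotation(15e6, 1000,
                               proportions = list(active = 0.04,
                                                  elongation = 0.06,
                                                  heterochromatin = 0.30),
                               seed = 21)
  cfg <- paint_config(bead_bp = 1000)
  p <- paint_beads(ann$track, cfg = cfg)    # state-13 rule for gray
  frac <- function(col) mean(vapply(p$colors, function(cs) col %in% cs,
                                    logical(1)))
  expect_equal(frac("pink"), 0.04, tolerance = 0.01)
  expect_equal(frac("light_green"), 0.06, tolerance = 0.01)
  expect_equal(frac("gray"), 0.30, tolerance = 0.01)
  # deterministic under seed
  ann2 <- synthesize_annotation(15e6, 1000,
                                proportions = list(active = 0.04,
                                                   elongation = 0.06,
                                                   heterochromatin = 0.30),
                                seed = 21)
  expect_identical(ann$track, ann2$track)
  expect_identical(unclass(ann$gc), unclass(ann2$gc))
  # GC profile is informative for the heterochromatin calibration
  thr <- calibrate_gc_threshold(ann$gc, ann$track, cfg)
  gray_by_gc <- unclass(ann$gc) < thr
  gray_by_state <- vapply(p$colors, function(cs) "gray" %in% cs, logical(1))
  expect_equal(mean(gray_by_gc), mean(gray_by_state), tolerance = 1e-6)
  expect_gt(cor(gray_by_gc, gray_by_state), 0.5)
})

test_that("zero-proportion synthesis paints all beads blue", {
  ann <- synthesize_annotation(1e6, 1000,
                               proportions = list(active = 0,
                                                  elongation = 0,
                                                  heterochromatin = 0),
                               seed = 1)
  p <- paint_beads(ann$track, cfg = paint_config(bead_bp = 1000))
  expect_true(all(vapply(p$colors, identical, logical(1), "blue")))
})

test_that("BED round trip parses both state-name dialects", {
  tf <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000\t1_Active_Promoter",
               "chr1\t1000\t2500\t13",
               "chr1\t2500\t3000\t9_Txn_Transition"), tf)
  tr <- read_state_track(tf)
  expect_equal(tr$state, c(1, 13, 9))   # normalized: sorted by start
  tf2 <- tempfile(fileext = ".bed")
  write_state_track(tr, tf2)
  expect_identical(read_state_track(tf2), tr)
  # painting is normalization/order independent
  tf3 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t2500\t3000\t9_Txn_Transition",
               "chr1\t0\t1000\t1_Active_Promoter",
               "chr1\t1000\t2500\t13"), tf3)
  expect_identical(read_state_track(tf3), tr)
})

test_that("painted fibers preserve multi-color beads and genomic spans", {
  cfg <- paint_config(bead_bp = 1000, gc_threshold = 0.45)
  tr <- covered_track(list(list(100, 250, 1)), n_bp = 3000)
  gc <- gc_track(c(0.40, 0.50, 0.50), 1000)
  p <- paint_beads(tr, gc, cfg)
  f <- painted_fiber(p)
  expect_setequal(f$colors[[1]], c("pink", "gray"))
  expect_equal(f$genomic$bead_bp, 1000)
  tf <- tempfile(fileext = ".tsv")
  write_painting(p, tf)
  out <- read.table(tf, sep = "\t")
  expect_equal(nrow(out), 3)
  expect_true(out[1, 4] %in% c("pink,gray", "gray,pink"))
})
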