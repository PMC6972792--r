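# Interval arithmetic: spec'd boundary behaviour and agreement with
# per-base boolean-mask oracles.

test_that("merge_intervals unions overlaps and bridges small gaps", {
  # BED [10,20) + [15,30) -> [10,30): 1-based 11-20 + 16-30 -> 11-30
  x <- make_intervals("chr1", c(10, 15), c(20, 30))
  m <- merge_intervals(x, 0)
  expect_equal(gr_df(m), data.frame(start = 11L, end = 30L))
  # BED [10,20) + [25,30), gap 5 < 10 -> [10,30)
  x2 <- make_intervals("chr1", c(10, 25), c(20, 30))
  expect_equal(gr_df(merge_intervals(x2, 10)),
               data.frame(start = 11L, end = 30L))
  # same gap with min_gap 0 stays split
  expect_equal(nrow(gr_df(merge_intervals(x2, 0))), 2L)
  expect_error(merge_intervals(x, -1), "non-negative")
})

test_that("intersect_intervals handles clipping and half-open boundaries", {
  a <- make_intervals("chr1", 0, 10)
  b <- make_intervals("chr1", 5, 20)
  expect_equal(gr_df(intersect_intervals(a, b, "overlap_regions")),
               data.frame(start = 6L, end = 10L))
  # book-ended BED intervals share no base
  b2 <- make_intervals("chr1", 10, 20)
  expect_length(intersect_intervals(a, b2, "overlap_regions"), 0L)
  expect_length(intersect_intervals(a, b2, "a_with_any_overlap"), 0L)
  # a_with_any_overlap returns a's members untouched
  got <- intersect_intervals(a, b, "a_with_any_overlap")
  expect_equal(gr_df(got), gr_df(a))
})

test_that("merge/intersect/subtract agree with per-base oracles", {
  set.seed(11)
  for (rep in 1:200) {
    L <- sample(500:10000, 1)
    a <- random_interval_set(sample(1:40, 1), L)
    b <- random_interval_set(sample(1:40, 1), L)
    ma <- mask_from_intervals(GenomicRanges::start(a), GenomicRanges::end(a), L)
    mb <- mask_from_intervals(GenomicRanges::start(b), GenomicRanges::end(b), L)
    expect_equal(gr_df(merge_intervals(a, 0)), runs_from_mask(ma))
    expect_equal(gr_df(intersect_intervals(a, b, "overlap_regions")),
                 runs_from_mask(ma & mb))
    keep <- !IRanges::overlapsAny(a, b)
    expect_equal(gr_df(subtract_blacklist(a, b)), gr_df(a[keep]))
  }
})

test_that("resize_intervals extends, shrinks, clips and drops", {
  # BED [100,112) +48 -> [52,160)
  x <- make_intervals("chr1", 100, 112)
  expect_equal(gr_df(resize_intervals(x, 48)), data.frame(start = 53L, end = 160L))
  # BED [52,160) -24 -> [76,136)
  y <- make_intervals("chr1", 52, 160)
  expect_equal(gr_df(resize_intervals(y, -24)), data.frame(start = 77L, end = 136L))
  # width would become negative -> dropped
  z <- make_intervals("chr1", 10, 20)
  expect_length(resize_intervals(z, -6), 0L)
  # clipped at position 0 and chromosome end
  w <- make_intervals("chr1", 5, 15, seqlengths = c(chr1 = 100L))
  got <- resize_intervals(w, 95)
  expect_equal(gr_df(got), data.frame(start = 1L, end = 100L))
})

test_that("refine_atac_regions composes clip, extend, merge, reduce", {
  region <- make_intervals("chr1", 90, 200)
  # single focal site BED [100,112) -> [76,136)
  small <- make_intervals("chr1", 100, 112)
  expect_equal(gr_df(refine_atac_regions(small, region)),
               data.frame(start = 77L, end = 136L))
  # two sites whose 48-bp extensions overlap fuse into one region
  small2 <- make_intervals("chr1", c(100, 150), c(112, 162))
  expect_equal(gr_df(refine_atac_regions(small2, region)),
               data.frame(start = 77L, end = 186L))
  expect_length(refine_atac_regions(small[0], region), 0L)
  # re-applying the merge geometry is a no-op
  out <- refine_atac_regions(small2, region)
  expect_equal(gr_df(merge_intervals(out, 0)), gr_df(out))
})

test_that("subtract_blacklist removes on >=1 bp overlap only", {
  peak <- make_intervals("chr1", 100, 300)
  expect_length(subtract_blacklist(peak, make_intervals("chr1", 250, 400)), 0L)
  # book-ended blacklist shares no base
  peak2 <- make_intervals("chr1", 100, 200)
  expect_length(subtract_blacklist(peak2, make_intervals("chr1", 200, 400)), 1L)
  expect_equal(gr_df(subtract_blacklist(peak, peak[0])), gr_df(peak))
})

test_that("filter_by_track keeps the boundary value on the kept side", {
  L <- 1000
  v <- rep(0.7, L); v[101:200] <- 0.9
  tr <- signal_track(list(chr1 = v))
  hi <- make_intervals("chr1", 100, 200)    # mean 0.9
  lo <- make_intervals("chr1", 500, 600)    # mean 0.7
  expect_length(filter_by_track(hi, tr, threshold = 0.8, keep = "ge"), 1L)
  expect_length(filter_by_track(lo, tr, threshold = 0.8, keep = "ge"), 0L)
  # exact boundary kept
  expect_length(filter_by_track(lo, tr, threshold = 0.7, keep = "ge"), 1L)
  # constant-1 track keeps everything at any threshold <= 1
  ones <- flat_track(1, L)
  expect_length(filter_by_track(c(hi, lo), ones, threshold = 1, keep = "ge"), 2L)
  expect_error(filter_by_track(make_intervals("chrX", 1, 10), tr, threshold = 0),
               "chrX")
})

test_that("annotate_window_signal bins agree with a per-base oracle", {
  L <- 2000
  # uniform value 1, window 100, bin 25 -> four bins of 25
  tr <- flat_track(1, L)
  x <- make_intervals("chr1", 900, 1000)
  expect_equal(annotate_window_signal(x, tr, window = 100, bin = 25),
               matrix(25, 1, 4))
  # delta spike of 7 at the interval center, count track, bin 1
  v <- numeric(L); v[951] <- 7
  ctr <- signal_track(list(chr1 = v), counts = TRUE)
  m <- annotate_window_signal(x, ctr, window = 50, bin = 1)
  expect_equal(sum(m > 0), 1L)
  expect_equal(max(m), normalize_counts(7, 7))
  # random track, row sums match windowed totals
  set.seed(3)
  v2 <- rpois(L, 2)
  tr2 <- signal_track(list(chr1 = as.numeric(v2)), counts = TRUE)
  iv <- random_interval_set(25, L, max_width = 60)
  got <- annotate_window_signal(iv, tr2, window = 200, bin = 25)
  mid0 <- (GenomicRanges::start(iv) - 1 + GenomicRanges::end(iv)) %/% 2
  for (i in seq_along(iv)) {
    w1 <- mid0[i] - 100 + 1
    expected <- sum(v2[max(w1, 1):min(w1 + 199, L)]) * 1e7 / sum(v2)
    expect_equal(sum(got[i, ]), expected, tolerance = 1e-9)
  }
  expect_error(annotate_window_signal(iv, tr2, window = 100, bin = 33), "divide")
})

test_that("frip counts tags in merged peaks and scales out", {
  v <- numeric(1000); v[101:200] <- 1; v[301:320] <- 1
  tr <- signal_track(list(chr1 = v), counts = TRUE)  # 120 tags
  all_peaks <- make_intervals("chr1", 0, 1000)
  expect_equal(frip(tr, all_peaks), 1.0)
  expect_equal(frip(tr, all_peaks[0]), 0.0)
  # 30 of 120 tags inside
  p <- make_intervals("chr1", 100, 130)
  expect_equal(frip(tr, p), 30 / 120)
  # invariant under uniform scaling
  tr5 <- signal_track(list(chr1 = v * 5), counts = TRUE)
  expect_equal(frip(tr5, p), frip(tr, p))
  # overlapping peaks do not double count
  expect_equal(frip(tr, c(p, p)), 30 / 120)
})

test_that("BED and bedGraph round-trip through files", {
  dir <- withr::local_tempdir()
  x <- make_intervals("chr1", c(10, 50), c(20, 80), strand = c("+", "-"),
                      name = c("a", "b"), score = c(1, 2))
  f <- file.path(dir, "x.bed")
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(gr_df(y), gr_df(x))
  expect_equal(as.character(GenomicRanges::strand(y)), c("+", "-"))
  v <- c(rep(0, 10), rep(2.5, 5), rep(0, 5), 1, rep(0, 9))
  tr <- signal_track(list(chr1 = v))
  g <- file.path(dir, "t.bedGraph")
  write_bedgraph(tr, g)
  tr2 <- read_bedgraph(g, chrom_lengths = c(chr1 = 30L))
  expect_equal(tr2$values$chr1, v)
})
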