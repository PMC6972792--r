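# Motif-class reduction, co-occurrence networks, homotypic pairs and the
# hypergeometric distance test.

test_that("pwm_correlation recognizes identity, shifts and degeneracy", {
  ps <- surrogate_partner_pwms()
  expect_equal(pwm_correlation(ps$GATA, ps$GATA), 1, tolerance = 1e-12)
  # shifted-by-one copy is recovered through the offset search
  g <- ps$GATA
  shifted <- pwm(rbind(c(0.25, 0.25, 0.25, 0.25), g$probs[-nrow(g$probs), ]),
                 name = "shift")
  expect_gt(pwm_correlation(shifted, g), 0.95)
  # uniform matrix has no variance -> NA
  unif <- pwm(matrix(0.25, 8, 4), name = "unif")
  expect_true(is.na(pwm_correlation(unif, g)))
})

test_that("reduce_to_classes assigns by best correlation above threshold", {
  ps <- surrogate_partner_pwms()
  known <- unname(ps)
  classes <- names(ps)
  got <- reduce_to_classes(list(ps$GATA, pwm(matrix(0.25, 8, 4), name = "u")),
                           known, classes)
  expect_equal(got$class, "GATA")
  expect_equal(got$correlation, 1, tolerance = 1e-12)
})

test_that("peak_class_matrix applies center-distance exclusions", {
  peaks <- make_intervals("chr1", 1000, 1200)
  anchor <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1094, width = 12),
                                   score = 10)  # center 1100
  mk <- function(centers, w = 8) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(centers - (w %/% 2), width = w))
  }
  # RUNX instance 20 bp from the anchor center counts
  m1 <- peak_class_matrix(peaks, anchor, list(RUNX = mk(1120)))
  expect_equal(unname(m1[1, "RUNX"]), 1L)
  # instance 3 bp from the anchor center is excluded (min_dist_co = 4)
  m2 <- peak_class_matrix(peaks, anchor, list(RUNX = mk(1103)))
  expect_equal(unname(m2[1, "RUNX"]), 0L)
  # two anchor motifs 5 bp apart collapse to one (min_dist_self = 6)
  two <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1094, 1099), width = 12),
                                score = c(10, 9))
  m3 <- peak_class_matrix(peaks, two, list(RUNX = mk(1150)))
  expect_equal(unname(m3[1, "anchor_n"]), 1L)
  # peaks without an anchor get a zero row
  far <- make_intervals("chr1", c(1000, 5000), c(1200, 5200))
  m4 <- peak_class_matrix(far, anchor, list(RUNX = mk(1120)))
  expect_equal(unname(m4[2, ]), c(0L, 0L))
})

test_that("build_network fractions match brute-force row counting", {
  mat <- cbind(RUNX = c(1L, 1L, 0L, 0L), GATA = c(1L, 1L, 1L, 1L),
               anchor_n = c(2L, 1L, 1L, 3L))
  net <- build_network(mat)
  expect_equal(net$nodes$fraction[net$nodes$class == "RUNX"], 0.5)
  expect_equal(net$nodes$fraction[net$nodes$class == "GATA"], 1.0)
  expect_equal(net$nodes$fraction[net$nodes$class == "anchor_x2"], 0.5)
  expect_equal(net$edges$fraction, 0.5)
  # disjoint halves: nodes 0.5 each, edge 0
  mat2 <- cbind(RUNX = c(1L, 1L, 0L, 0L), GATA = c(0L, 0L, 1L, 1L),
                anchor_n = rep(1L, 4))
  expect_equal(build_network(mat2)$edges$fraction, 0)
  # random matrices: edge <= min(nodes), equals row enumeration
  set.seed(12)
  for (i in 1:20) {
    m <- cbind(A = rbinom(30, 1, 0.4), B = rbinom(30, 1, 0.6),
               anchor_n = rpois(30, 1))
    net <- build_network(m)
    eAB <- mean(m[, "A"] == 1 & m[, "B"] == 1)
    expect_equal(net$edges$fraction, eAB)
    expect_lte(net$edges$fraction, min(net$nodes$fraction[1:2]))
  }
  expect_error(build_network(mat[0, , drop = FALSE]), "empty")
})

test_that("enumerate_pairs and single_motifs follow the distance rules", {
  m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 130), width = 12),
                              strand = c("+", "+"), score = c(5, 6))
  p <- enumerate_pairs(m)
  expect_equal(nrow(p), 1L)
  expect_equal(p$distance, 30L)
  expect_equal(p$orientation, "same")
  # 200 bp apart: no pair, both single
  m2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 300), width = 12))
  expect_equal(nrow(enumerate_pairs(m2)), 0L)
  expect_length(single_motifs(m2), 2L)
  # three motifs at 100/140/170: all three pairings, none single
  m3 <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100, 140, 170), width = 12),
                               strand = c("+", "-", "+"))
  p3 <- enumerate_pairs(m3)
  expect_equal(nrow(p3), 3L)
  expect_setequal(p3$distance, c(40L, 30L, 70L))
  expect_length(single_motifs(m3), 0L)
  expect_equal(sort(p3$orientation), c("opposite", "opposite", "same"))
})

test_that("distance enrichment p-values match exact combinatorial sums", {
  # N = 100 pairs, 10 at distance d, 20 bound, 6 bound at d
  mk_pairs <- function(N, m, n, q) {
    d <- c(rep(30L, m), rep(80L, N - m))
    bound <- logical(N)
    bound[seq_len(q)] <- TRUE                    # q bound at distance 30
    bound[(m + 1):(m + (n - q))] <- TRUE         # rest of the bound at 80
    data.frame(distance = d, bound = bound)
  }
  pr <- mk_pairs(100, 10, 20, 6)
  res <- distance_enrichment(pr)
  exact <- sum(vapply(6:10, function(i)
    choose(10, i) * choose(90, 20 - i), 0)) / choose(100, 20)
  expect_equal(res$table$pvalue[res$table$distance == 30], exact,
               tolerance = 1e-12)
  # q = 0 -> p = 1, never significant
  pr0 <- mk_pairs(100, 10, 20, 0)
  r0 <- distance_enrichment(pr0)
  expect_equal(r0$table$pvalue[r0$table$distance == 30], 1)
  expect_false(r0$table$significant[r0$table$distance == 30])
  # partition property: per-distance counts sum to the total
  expect_equal(sum(res$table$n_at_d), nrow(pr))
  expect_error(distance_enrichment(data.frame(distance = 1L, bound = TRUE)),
               "bound")
})

test_that("classify_pairs_bound keeps concordant pairs only", {
  m <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(c(100, 140, 500, 540, 900, 940),
                                               width = 12))
  peaks <- make_intervals("chr1", c(80, 890), c(220, 1000))
  p <- enumerate_pairs(m)
  got <- classify_pairs_bound(p, m, peaks)
  # pairs (100,140) bound, (900,940) bound, (500,540) unbound
  expect_equal(nrow(got), 3L)
  expect_equal(sum(got$bound), 2L)
  # a mixed pair is dropped
  peaks2 <- make_intervals("chr1", 80, 120)   # covers only the first member
  got2 <- classify_pairs_bound(p, m, peaks2)
  expect_equal(nrow(got2), 2L)
})
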