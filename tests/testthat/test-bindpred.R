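# Logistic binding prediction: IRLS fitting, ROC/AUC and predictor-set
# comparisons.

sim_logistic <- function(n, b0 = -2, b1 = 1.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(b0 + b1 * x))
  data.frame(score = x, bound = y)
}

test_that("roc_auc matches pairwise concordance and handles edge cases", {
  tab <- data.frame(bound = c(1, 1, 0, 0))
  model <- structure(list(name = "id", coefficients = c(`(Intercept)` = 0, s = 1),
                          predictors = "s", train = integer(), seed = 1),
                     class = "logistic_model")
  tab$s <- c(0.9, 0.8, 0.4, 0.3)
  expect_equal(roc_auc(model, tab, eval = 1:4)$auc, 1.0)
  tab$s <- c(0.9, 0.35, 0.4, 0.3)
  expect_equal(roc_auc(model, tab, eval = 1:4)$auc, 0.75)
  # AUC equals the Mann-Whitney statistic on random data
  set.seed(41)
  for (i in 1:10) {
    n <- 60
    tab2 <- data.frame(s = rnorm(n), bound = rbinom(n, 1, 0.5))
    if (length(unique(tab2$bound)) < 2) next
    r <- roc_auc(model, tab2, eval = seq_len(n))
    pos <- tab2$s[tab2$bound == 1]; neg <- tab2$s[tab2$bound == 0]
    conc <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, conc, tolerance = 1e-9)
    # curve is monotone
    expect_true(!is.unsorted(r$fpr))
    expect_true(!is.unsorted(r$tpr))
    # cross-check against an established implementation
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(tab2$bound, tab2$s,
                                            quiet = TRUE, direction = "<")))
      expect_equal(r$auc, ref, tolerance = 1e-9)
    }
  }
  expect_error(roc_auc(model, data.frame(s = 1:3, bound = c(1, 1, 1)),
                       eval = 1:3), "single class")
})

test_that("null scores give AUC near one half", {
  set.seed(47)
  tab <- data.frame(s = rnorm(10000), bound = rbinom(10000, 1, 0.4))
  model <- structure(list(name = "id", coefficients = c(`(Intercept)` = 0, s = 1),
                          predictors = "s", train = integer(), seed = 1),
                     class = "logistic_model")
  expect_equal(roc_auc(model, tab, eval = 1:10000)$auc, 0.5, tolerance = 0.02)
})

test_that("fit_logistic handles canonical cases", {
  # intercept-only at 50% positives: intercept ~ logit(0.5) = 0
  tab <- data.frame(bound = rep(c(0, 1), 50), dummy = 0)
  m <- fit_logistic(tab, "dummy", train = 1:100)
  expect_equal(unname(m$coefficients["(Intercept)"]), 0, tolerance = 1e-6)
  # separable data: ridge keeps coefficients finite, fit saturates
  tab2 <- data.frame(bound = rep(c(0, 1), 50), x = rep(c(-1, 1), 50))
  m2 <- fit_logistic(tab2, "x", train = 1:100)
  p <- predict(m2, tab2)
  expect_true(all(p[tab2$bound == 1] > 0.99))
  expect_true(all(is.finite(m2$coefficients)))
  # single-class training errors
  tab3 <- data.frame(bound = rep(1, 20), x = rnorm(20))
  expect_error(fit_logistic(tab3, "x", train = 1:20), "single class")
  # agreement with glm on a well-conditioned problem
  tab4 <- sim_logistic(3000, seed = 5)
  m4 <- fit_logistic(tab4, "score", train = seq_len(3000))
  ref <- stats::glm(bound ~ score, binomial, tab4)
  expect_equal(unname(m4$coefficients), unname(coef(ref)), tolerance = 1e-4)
})

test_that("coefficients are recovered from simulated data", {
  tab <- sim_logistic(40000, b0 = -2, b1 = 1.5, seed = 7)
  m <- fit_logistic(tab, "score", split_seed = 3)  # trains on 20,000 rows
  expect_equal(unname(m$coefficients["(Intercept)"]), -2, tolerance = 0.1)
  expect_equal(unname(m$coefficients["score"]), 1.5, tolerance = 0.1)
})

test_that("adding predictors never lowers training likelihood", {
  set.seed(51)
  n <- 2000
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
  tab$bound <- rbinom(n, 1, plogis(-1 + tab$x1 + 0.5 * tab$x2))
  train <- seq_len(n)
  loglik <- function(m) {
    p <- predict(m, tab)
    sum(log(ifelse(tab$bound == 1, p, 1 - p)))
  }
  l1 <- loglik(fit_logistic(tab, "x1", train = train))
  l2 <- loglik(fit_logistic(tab, c("x1", "x2"), train = train))
  l3 <- loglik(fit_logistic(tab, c("x1", "x2", "noise"), train = train))
  expect_gte(l2, l1 - 1e-6)
  expect_gte(l3, l2 - 1e-6)
})

test_that("compare_predictor_sets shares splits and is deterministic", {
  set.seed(53)
  n <- 1200
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  tab$bound <- rbinom(n, 1, plogis(tab$x1))
  sets <- list(a = "x1", a_again = "x1", ab = c("x1", "x2"))
  got <- compare_predictor_sets(tab, sets, split_seed = 2)
  # duplicated predictor set -> identical AUC
  expect_equal(got$auc[1], got$auc[2], tolerance = 1e-12)
  got2 <- compare_predictor_sets(tab, sets, split_seed = 2)
  expect_equal(got$auc, got2$auc, tolerance = 1e-12)
  # multi-split averaging returns the per-split matrix
  got3 <- compare_predictor_sets(tab, sets, split_seed = 2, n_splits = 3)
  expect_equal(dim(attr(got3, "auc_by_split")), c(3L, 3L))
  expect_equal(got3$auc, unname(colMeans(attr(got3, "auc_by_split"))))
})

test_that("assemble_features builds labels, bands and windows correctly", {
  L <- 6000
  g_matches <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 3000), width = 12),
    score = c(8, 7))   # centers 1006, 3006
  cons <- signal_track(list(chr1 = rep(0.5, L)))
  # one co-motif 50 bp from the first center, one 5 bp from the second
  cls <- list(RUNX = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1052, 3007), width = 8)))  # centers 1056, 3011
  v <- numeric(L); v[1001:1010] <- 2
  atac_pre <- signal_track(list(chr1 = v), counts = TRUE)
  atac_post <- signal_track(list(chr1 = c(numeric(L - 1), 1)), counts = TRUE)
  peaks <- make_intervals("chr1", 990, 1100)
  ft <- assemble_features(g_matches, cons, cls, atac_pre, atac_post, peaks)
  expect_equal(ft$bound, c(1L, 0L))
  expect_equal(ft$RUNX, c(1L, 0L))   # 5 bp is below the 6-bp band floor
  expect_equal(ft$conservation, c(0.5, 0.5))
  expect_equal(ft$atac_pre[1], normalize_counts(sum(v), sum(v)))
  expect_equal(ft$atac_post, c(0, 0))
})
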