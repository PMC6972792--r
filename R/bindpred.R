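#' Assemble the per-motif feature table for binding prediction
#'
#' One row per candidate motif: log-odds score, mean conservation over the
#' motif, binary presence of each co-associated motif class within 6-100 bp
#' of the motif center, accessibility before and after induction (tags per
#' 10^7 in a 50-bp motif-centered window), and the bound label (overlap
#' with a stringent peak).
#'
#' @param matches `GRanges` of candidate motifs (mappability-filtered) with
#'   a `score` column.
#' @param conservation Ratio `signal_track` of per-base conservation.
#' @param class_matches Named list of `GRanges`, one per co-motif class.
#' @param atac_pre,atac_post Count `signal_track`s of Tn5 cuts.
#' @param peaks_stringent `GRanges` of stringent binding peaks.
#' @param acc_window Accessibility window width (default 50).
#' @param co_min,co_max Center-distance band for co-motif flags
#'   (default 6-100 bp).
#' @return A data frame with columns `score`, `conservation`, one 0/1
#'   column per class, `atac_pre`, `atac_post`, `bound`.
#' @export
assemble_features <- function(matches, conservation, class_matches,
                              atac_pre, atac_post, peaks_stringent,
                              acc_window = 50, co_min = 6, co_max = 100) {
  stopifnot(length(matches) > 0)
  score <- S4Vectors::mcols(matches)$score
  if (is.null(score)) stop("matches need a `score` column")
  cons <- interval_means(conservation, matches)
  ctr <- .centers(matches)
  chroms <- as.character(GenomicRanges::seqnames(matches))
  co <- matrix(0L, nrow = length(matches), ncol = length(class_matches),
               dimnames = list(NULL, names(class_matches)))
  win <- GenomicRanges::GRanges(chroms,
                                IRanges::IRanges(pmax(ctr - co_max, 1L), ctr + co_max))
  for (k in seq_along(class_matches)) {
    cm <- class_matches[[k]]
    cc <- .centers(cm)
    hits <- GenomicRanges::findOverlaps(
      win, GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(cm)),
                                  IRanges::IRanges(cc, cc)),
      ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    dist_ok <- abs(cc[sh] - ctr[qh]) >= co_min & abs(cc[sh] - ctr[qh]) <= co_max
    co[unique(qh[dist_ok]), k] <- 1L
  }
  acc <- function(track) {
    rowSums(annotate_window_signal(matches, track, window = acc_window,
                                   bin = acc_window))
  }
  out <- data.frame(score = score, conservation = cons)
  for (k in colnames(co)) out[[k]] <- co[, k]
  out$atac_pre <- acc(atac_pre)
  out$atac_post <- acc(atac_post)
  out$bound <- as.integer(IRanges::overlapsAny(matches, peaks_stringent,
                                               ignore.strand = TRUE))
  bad <- which(!stats::complete.cases(out) |
                 !apply(out, 1, function(r) all(is.finite(as.numeric(r)))))
  if (length(bad))
    stop("missing/non-finite features for motif row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  out
}

#' Deterministic random half split
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return Integer vector of training indices (`floor(n/2)` of them); the
#'   remaining rows form the evaluation half.
#' @export
split_half <- function(n, seed = 1L) {
  with_local_seed(seed, sort(sample.int(n, n %/% 2)))
}

#' Fit a ridge-stabilized logistic model
#'
#' Maximizes the Bernoulli log-likelihood with a small ridge penalty on the
#' non-intercept coefficients (so separable training halves stay finite) by
#' iteratively reweighted least squares, to a gradient-norm tolerance of
#' 1e-8.
#'
#' @param table Feature table (see [assemble_features()]) with a `bound`
#'   column.
#' @param predictors Character vector of feature column names.
#' @param train Integer indices of training rows; defaults to a seeded
#'   random half.
#' @param split_seed Seed used when `train` is NULL.
#' @param lambda Ridge penalty (default 1e-6).
#' @param max_iter Maximum IRLS iterations.
#' @param name Label for the predictor set.
#' @return An object of class `logistic_model`: `name`, `coefficients`,
#'   `predictors`, `train`, `seed`, `converged`, `iterations`.
#' @export
fit_logistic <- function(table, predictors, train = NULL, split_seed = 1L,
                         lambda = 1e-6, max_iter = 100, name = "model") {
  stopifnot(all(predictors %in% names(table)), "bound" %in% names(table))
  if (is.null(train)) train <- split_half(nrow(table), split_seed)
  y <- table$bound[train]
  if (length(unique(y)) < 2) stop("training half contains a single class")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[train, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  p <- ncol(X)
  D <- diag(c(0, rep(lambda, p - 1)), nrow = p)
  beta <- numeric(p)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - drop(D %*% beta)
    if (sqrt(sum(grad^2)) < 1e-8) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + D
    beta <- beta + solve(H, grad)
  }
  if (!converged) {
    eta <- drop(X %*% beta)
    grad <- drop(crossprod(X, y - stats::plogis(eta))) - drop(D %*% beta)
    if (sqrt(sum(grad^2)) < 1e-8) converged <- TRUE
  }
  if (!converged)
    stop("IRLS did not converge in ", max_iter, " iterations (|grad| = ",
         format(sqrt(sum(grad^2))), ", max |beta| = ",
         format(max(abs(beta))), ")")
  structure(list(name = name,
                 coefficients = stats::setNames(drop(beta), colnames(X)),
                 predictors = predictors, train = train, seed = split_seed,
                 converged = converged, iterations = it),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model", x$name, "(", length(x$train), "training rows )\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted binding probabilities
#'
#' @param object A `logistic_model`.
#' @param newdata Feature table.
#' @param ... Unused.
#' @return Vector of fitted probabilities.
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[, object$predictors, drop = FALSE]))
  stats::plogis(drop(X %*% object$coefficients))
}

#' ROC curve and AUC on the held-out half
#'
#' Evaluates the model on the rows not used for training. The AUC equals
#' the probability that a random bound motif outscores a random unbound
#' one (ties counted 1/2, the Mann-Whitney statistic); the curve is a
#' threshold sweep over the predicted probabilities.
#'
#' @param model A `logistic_model`.
#' @param table The full feature table the model was fitted on.
#' @param eval Optional evaluation indices (defaults to the complement of
#'   the training rows).
#' @return A list of class `roc_result`: `thresholds`, `fpr`, `tpr`,
#'   `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(model, table, eval = NULL) {
  if (is.null(eval)) eval <- setdiff(seq_len(nrow(table)), model$train)
  y <- table$bound[eval]
  if (length(unique(y)) < 2) stop("evaluation set contains a single class")
  s <- predict(model, table[eval, , drop = FALSE])
  .roc_from_scores(s, y)
}

# ROC/AUC from raw scores and 0/1 labels
.roc_from_scores <- function(s, y) {
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  o <- order(s, decreasing = TRUE)
  tp <- cumsum(y[o] == 1)
  fp <- cumsum(y[o] == 0)
  keep <- c(diff(s[o]) != 0, TRUE)   # one point per distinct threshold
  structure(list(thresholds = s[o][keep],
                 fpr = c(0, fp[keep] / n_neg),
                 tpr = c(0, tp[keep] / n_pos),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result: AUC =", round(x$auc, 4),
      "(", x$n_pos, "pos /", x$n_neg, "neg )\n")
  invisible(x)
}

#' Default nested predictor sets
#'
#' @param class_names Names of the co-motif class columns.
#' @return Named list of predictor vectors: sequence-only (score,
#'   conservation, co-motifs), plus pre-induction accessibility, plus both
#'   accessibility conditions.
#' @export
default_predictor_sets <- function(class_names) {
  seq_only <- c("score", "conservation", class_names)
  list(sequence = seq_only,
       sequence_pre = c(seq_only, "atac_pre"),
       sequence_pre_post = c(seq_only, "atac_pre", "atac_post"))
}

#' Compare predictor sets on shared train/test splits
#'
#' Fits one logistic model per predictor set on a seeded random half and
#' reports the held-out AUC of each; all sets share the same split(s).
#' With `n_splits > 1` the procedure is repeated over independent seeded
#' half splits and the mean AUC per set is reported, which removes the
#' dependence of the comparison on one particular split.
#'
#' @param table Feature table.
#' @param sets Named list of predictor vectors (>= 2 sets).
#' @param split_seed Base seed for the shared half split(s).
#' @param n_splits Number of repeated random halves to average over.
#' @return A data frame (`set`, `auc`, `seed`), one row per set in the
#'   given order (`auc` is the mean over splits), with the first split's
#'   fitted models in `attr(, "models")`, its ROC results in
#'   `attr(, "rocs")` and the per-split AUC matrix in
#'   `attr(, "auc_by_split")`.
#' @export
compare_predictor_sets <- function(table, sets, split_seed = 1L,
                                   n_splits = 1L) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)), n_splits >= 1)
  auc_mat <- matrix(NA_real_, nrow = n_splits, ncol = length(sets),
                    dimnames = list(NULL, names(sets)))
  models1 <- rocs1 <- NULL
  for (k in seq_len(n_splits)) {
    train <- split_half(nrow(table), split_seed + (k - 1L) * 1000L)
    models <- lapply(names(sets), function(nm)
      fit_logistic(table, sets[[nm]], train = train, name = nm))
    rocs <- lapply(models, roc_auc, table = table)
    auc_mat[k, ] <- vapply(rocs, function(r) r$auc, 0)
    if (k == 1L) {
      models1 <- stats::setNames(models, names(sets))
      rocs1 <- stats::setNames(rocs, names(sets))
    }
  }
  out <- data.frame(set = names(sets), auc = unname(colMeans(auc_mat)),
                    seed = split_seed, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "models") <- models1
  attr(out, "rocs") <- rocs1
  attr(out, "auc_by_split") <- auc_mat
  out
}
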