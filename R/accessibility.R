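#' Tn5 cut positions from read coordinates
#'
#' Shifts read ends to the transposase binding site: a plus-strand read
#' cuts 4 bases downstream of its 5' end, a minus-strand read 4 bases
#' upstream of its 5' end (the classic +4/-5 adjustment expressed in
#' 1-based closed coordinates: `start + 4` and `end - 4`).
#'
#' @param start,end 1-based closed read coordinates (`end >= start`).
#' @param strand `"+"` or `"-"` per read.
#' @return Integer vector of cut positions.
#' @export
tn5_shift <- function(start, end, strand) {
  stopifnot(all(end >= start))
  ifelse(strand == "+", start + 4L, end - 4L)
}

#' Build a cut-site track from cut positions
#'
#' @param cuts Data frame with columns `chrom` and `pos` (1-based cut
#'   positions), e.g. from [tn5_shift()].
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A count `signal_track` of per-base cut counts.
#' @export
cut_track <- function(cuts, chrom_lengths) {
  vals <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    p <- cuts$pos[cuts$chrom == ch]
    p <- p[p >= 1 & p <= length(v)]
    if (length(p)) {
      t <- tabulate(p, nbins = length(v))
      v <- as.numeric(t)
    }
    v
  })
  names(vals) <- names(chrom_lengths)
  signal_track(vals, counts = TRUE)
}

#' Pre/post accessibility count matrix over peak-centered windows
#'
#' @param peaks `GRanges` of peaks.
#' @param pre,post Count `signal_track`s of Tn5 cuts before and after
#'   induction.
#' @param window Window width centered on each peak midpoint (default 300).
#' @return Numeric matrix `length(peaks)` x 2 (columns `pre`, `post`) of
#'   library-normalized (tags per 10^7) cut counts.
#' @export
peak_count_matrix <- function(peaks, pre, post, window = 300) {
  m <- cbind(
    pre = rowSums(annotate_window_signal(peaks, pre, window = window, bin = window)),
    post = rowSums(annotate_window_signal(peaks, post, window = window, bin = window)))
  rownames(m) <- NULL
  m
}

#' Remodeling index
#'
#' Signed per-peak summary of the accessibility change after induction:
#' `log2((post + 1) / (pre + 1))` on library-normalized window counts. Zero
#' means no change; +1 a doubling of accessibility.
#'
#' @param pre,post Normalized cut counts (vectors of equal length).
#' @return Numeric vector of remodeling indices.
#' @export
remodeling_index <- function(pre, post) {
  stopifnot(all(pre >= 0), all(post >= 0))
  log2((post + 1) / (pre + 1))
}

#' K-means clustering of peak accessibility
#'
#' Clusters the two-column (pre, post) accessibility matrix with K-means on
#' log2(x+1)-transformed counts (10 restarts, best inertia kept), then
#' relabels clusters 1..K by increasing mean pre-induction accessibility so
#' cluster order reflects the closed-to-open spectrum before induction.
#'
#' @param mat Matrix from [peak_count_matrix()] (normalized counts,
#'   columns pre and post).
#' @param K Number of clusters (default 14).
#' @param seed Integer seed fixing the restarts.
#' @param nstart Number of random restarts.
#' @return A list of class `cluster_model`: `K`, `assignment` (1..K per
#'   peak), `summary` (per-cluster size, mean pre, mean post, `rem_index` =
#'   mean per-peak remodeling index), `seed`.
#' @export
cluster_peaks <- function(mat, K = 14, seed = 1L, nstart = 10) {
  stopifnot(K >= 1, ncol(mat) == 2)
  if (nrow(mat) < K) stop("fewer rows (", nrow(mat), ") than clusters (", K, ")")
  lg <- log2(mat + 1)
  if (K == 1) {
    cl <- rep(1L, nrow(mat))
  } else {
    km <- with_local_seed(seed, stats::kmeans(lg, centers = K, nstart = nstart,
                                              iter.max = 100))
    cl <- km$cluster
  }
  # relabel by increasing mean pre-induction accessibility
  pre_means <- tapply(mat[, 1], cl, mean)
  new_id <- stats::setNames(rank(pre_means, ties.method = "first"),
                            names(pre_means))
  cl <- as.integer(new_id[as.character(cl)])
  ri <- remodeling_index(mat[, 1], mat[, 2])
  summ <- data.frame(
    cluster = seq_len(K),
    n = as.integer(table(factor(cl, levels = seq_len(K)))),
    mean_pre = as.numeric(tapply(mat[, 1], factor(cl, levels = seq_len(K)), mean)),
    mean_post = as.numeric(tapply(mat[, 2], factor(cl, levels = seq_len(K)), mean)),
    rem_index = as.numeric(tapply(ri, factor(cl, levels = seq_len(K)), mean)))
  structure(list(K = K, assignment = cl, summary = summ, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: K =", x$K, ",", length(x$assignment), "peaks\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Single-base footprint profile around motif matches
#'
#' Per-base, library-normalized cut counts in strand-oriented windows
#' centered on each match (minus-strand windows are reversed), averaged
#' over matches. Protein occupancy shows as a central depletion (the
#' footprint) flanked by elevated accessibility.
#'
#' @param matches Non-empty `GRanges` of motif matches.
#' @param cuts Count `signal_track` of Tn5 cuts.
#' @param window Flank size; the profile covers positions `-window..window`
#'   relative to the motif center.
#' @return A data frame with `offset` and `value` (mean normalized cuts per
#'   motif), of class `footprint_profile`.
#' @export
footprint_profile <- function(matches, cuts, window = 100) {
  if (length(matches) == 0L) stop("empty match set")
  width <- 2L * window + 1L
  mid0 <- (GenomicRanges::start(matches) - 1L + GenomicRanges::end(matches)) %/% 2L
  centers <- mid0 + 1L  # 1-based center base
  chroms <- as.character(GenomicRanges::seqnames(matches))
  minus <- as.character(GenomicRanges::strand(matches)) == "-"
  prof <- numeric(width)
  for (ch in unique(chroms)) {
    v <- cuts$values[[ch]]
    if (is.null(v)) stop("cut track does not cover chromosome ", ch)
    idx <- which(chroms == ch)
    for (i in idx) {
      s <- centers[i] - window
      pos <- s:(s + width - 1L)
      ok <- pos >= 1L & pos <= length(v)
      row <- numeric(width)
      row[ok] <- v[pos[ok]]
      if (minus[i]) row <- rev(row)
      prof <- prof + row
    }
  }
  prof <- normalize_counts(prof, cuts$library_size) / length(matches)
  structure(data.frame(offset = -window:window, value = prof),
            class = c("footprint_profile", "data.frame"),
            n_motifs = length(matches))
}
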