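#' Best alignment correlation between two PWMs
#'
#' Maximum Pearson correlation of the flattened, aligned probability
#' matrices over all relative offsets (up to half the shorter width) and
#' both orientations of the second matrix. At least four overlapping
#' columns are required per alignment.
#'
#' @param a,b `pwm` objects.
#' @return Best correlation in `[-1, 1]`, or `NA` if every alignment is
#'   degenerate (e.g. a uniform matrix has zero variance).
#' @export
pwm_correlation <- function(a, b) {
  best <- NA_real_
  max_off <- min(pwm_width(a), pwm_width(b)) %/% 2
  for (bb in list(b, pwm_reverse_complement(b))) {
    for (off in -max_off:max_off) {
      ia <- seq_len(pwm_width(a))
      ib <- ia + off
      ok <- ib >= 1 & ib <= pwm_width(bb)
      if (sum(ok) < 4) next
      va <- as.vector(t(a$probs[ia[ok], , drop = FALSE]))
      vb <- as.vector(t(bb$probs[ib[ok], , drop = FALSE]))
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
      r <- stats::cor(va, vb)
      if (is.na(best) || r > best) best <- r
    }
  }
  best
}

#' Reduce discovered PWMs to known motif classes
#'
#' Assigns each PWM to the class of its best-correlated known motif when
#' that correlation exceeds `r_threshold`; unmatched PWMs are dropped.
#'
#' @param pwms List of candidate `pwm` objects.
#' @param known List of reference `pwm` objects.
#' @param classes Character vector of class labels, one per `known` entry.
#' @param r_threshold Minimum (strict) correlation for a match.
#' @return A data frame with one row per retained PWM: `motif`, `class`,
#'   `correlation`.
#' @export
reduce_to_classes <- function(pwms, known, classes, r_threshold = 0.85) {
  stopifnot(length(known) == length(classes))
  rows <- lapply(pwms, function(p) {
    rs <- vapply(known, function(k) pwm_correlation(p, k), 0)
    if (all(is.na(rs))) return(NULL)
    best <- which.max(rs)
    if (is.na(rs[best]) || rs[best] <= r_threshold) return(NULL)
    data.frame(motif = p$name, class = classes[best],
               correlation = rs[best], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(motif = character(), class = character(),
                      correlation = numeric()))
  do.call(rbind, rows)
}

# 1-based center position of each interval
.centers <- function(x) {
  (GenomicRanges::start(x) - 1L + GenomicRanges::end(x)) %/% 2L + 1L
}

#' Per-peak motif-class co-occurrence matrix
#'
#' For every peak carrying an anchor motif, records which motif classes
#' have at least one instance whose center lies at least `min_dist_co`
#' bases from the anchor center (so the anchor's own footprint is not
#' double-counted), plus the number of anchor-motif occurrences spaced at
#' least `min_dist_self` apart (greedy left-to-right selection).
#'
#' @param peaks `GRanges` of peaks.
#' @param anchor_matches `GRanges` of anchor (e.g. PU.1) motif matches.
#' @param class_matches Named list of `GRanges`, one per motif class.
#' @param min_dist_co Minimum center distance anchor-to-co-motif (default 4).
#' @param min_dist_self Minimum center distance between counted anchor
#'   motifs (default 6).
#' @return Integer matrix `length(peaks)` x `(classes + 1)`; class columns
#'   are 0/1, the last column `anchor_n` counts anchor motifs. Peaks
#'   without an anchor match get a zero row.
#' @export
peak_class_matrix <- function(peaks, anchor_matches, class_matches,
                              min_dist_co = 4, min_dist_self = 6) {
  ncls <- length(class_matches)
  out <- matrix(0L, nrow = length(peaks), ncol = ncls + 1L,
                dimnames = list(NULL, c(names(class_matches), "anchor_n")))
  if (length(peaks) == 0L) return(out)
  anc_hit <- GenomicRanges::findOverlaps(peaks, anchor_matches,
                                         ignore.strand = TRUE)
  anc_ctr <- .centers(anchor_matches)
  anc_score <- S4Vectors::mcols(anchor_matches)$score
  if (is.null(anc_score)) anc_score <- rep(0, length(anchor_matches))
  cls_hits <- lapply(class_matches, function(g)
    GenomicRanges::findOverlaps(peaks, g, ignore.strand = TRUE))
  cls_ctrs <- lapply(class_matches, .centers)
  for (i in seq_along(peaks)) {
    aj <- S4Vectors::subjectHits(anc_hit)[S4Vectors::queryHits(anc_hit) == i]
    if (!length(aj)) next
    # reference anchor = best-scoring anchor match in the peak
    ref <- aj[which.max(anc_score[aj])]
    ref_ctr <- anc_ctr[ref]
    for (k in seq_len(ncls)) {
      cj <- S4Vectors::subjectHits(cls_hits[[k]])[
        S4Vectors::queryHits(cls_hits[[k]]) == i]
      if (length(cj) &&
          any(abs(cls_ctrs[[k]][cj] - ref_ctr) >= min_dist_co))
        out[i, k] <- 1L
    }
    # greedy left-to-right count of anchor motifs >= min_dist_self apart
    ctrs <- sort(anc_ctr[aj])
    cnt <- 0L
    last <- -Inf
    for (p in ctrs) {
      if (p - last >= min_dist_self) {
        cnt <- cnt + 1L
        last <- p
      }
    }
    out[i, ncls + 1L] <- cnt
  }
  out
}

#' Motif co-association network summaries
#'
#' Node size = fraction of peaks containing the class; edge width =
#' fraction of peaks containing both classes of the pair. An extra
#' `anchor_x2` node gives the fraction of peaks with at least two anchor
#' motifs.
#'
#' @param mat Matrix from [peak_class_matrix()].
#' @return A list with data frames `nodes` (`class`, `fraction`) and
#'   `edges` (`a`, `b`, `fraction`).
#' @export
build_network <- function(mat) {
  if (nrow(mat) == 0L) stop("empty peak-class matrix")
  cls <- setdiff(colnames(mat), "anchor_n")
  pres <- mat[, cls, drop = FALSE] > 0
  nodes <- data.frame(class = cls, fraction = colMeans(pres),
                      row.names = NULL, stringsAsFactors = FALSE)
  nodes <- rbind(nodes, data.frame(
    class = "anchor_x2", fraction = mean(mat[, "anchor_n"] >= 2)))
  if (length(cls) >= 2) {
    pairs <- utils::combn(cls, 2)
    edges <- data.frame(
      a = pairs[1, ], b = pairs[2, ],
      fraction = apply(pairs, 2, function(p) mean(pres[, p[1]] & pres[, p[2]])),
      stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(), b = character(), fraction = numeric())
  }
  list(nodes = nodes, edges = edges)
}

#' Homotypic motif pairs and single motifs
#'
#' Enumerates all ordered pairs of matches on one chromosome whose 5'
#' start coordinates (reference strand) lie within `max_dist` bases;
#' distance is the start-to-start difference, so two non-overlapping
#' 12-mers are at distance >= 12. Orientation is `same` when both strands
#' agree, `opposite` otherwise.
#'
#' @param matches `GRanges` of matches of one motif.
#' @param max_dist Maximum pair distance in bases (default 150).
#' @return A data frame: `chrom`, `start_a`, `start_b` (1-based),
#'   `index_a`, `index_b` (positions in `matches`), `distance`,
#'   `orientation`, `score_a`, `score_b`.
#' @export
enumerate_pairs <- function(matches, max_dist = 150) {
  chroms <- as.character(GenomicRanges::seqnames(matches))
  st <- GenomicRanges::start(matches)
  strand <- as.character(GenomicRanges::strand(matches))
  score <- S4Vectors::mcols(matches)$score
  if (is.null(score)) score <- rep(NA_real_, length(matches))
  rows <- list()
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    o <- i[order(st[i])]
    s <- st[o]
    for (a in seq_along(o)) {
      b <- a + 1L
      while (b <= length(o) && s[b] - s[a] <= max_dist) {
        if (s[b] > s[a]) {   # identical starts (opposite strands) are not a spacing
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, start_a = s[a], start_b = s[b],
            index_a = o[a], index_b = o[b],
            distance = s[b] - s[a],
            orientation = if (strand[o[a]] == strand[o[b]]) "same" else "opposite",
            score_a = score[o[a]], score_b = score[o[b]],
            stringsAsFactors = FALSE)
        }
        b <- b + 1L
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start_a = integer(),
                      start_b = integer(), index_a = integer(),
                      index_b = integer(), distance = integer(),
                      orientation = character(), score_a = numeric(),
                      score_b = numeric()))
  do.call(rbind, rows)
}

#' @rdname enumerate_pairs
#' @return `single_motifs` returns the subset of `matches` with no other
#'   match within `max_dist` bases (start-to-start).
#' @export
single_motifs <- function(matches, max_dist = 150) {
  matches[.nearest_start_distance(matches) > max_dist]
}

#' Classify pairs as bound or unbound by peak overlap
#'
#' A pair is `bound` when both members fall inside a peak, `unbound` when
#' neither does; mixed pairs (exactly one member in a peak) are excluded
#' from the enrichment analysis.
#'
#' @param pairs Data frame from [enumerate_pairs()].
#' @param matches The `GRanges` the pairs were enumerated from.
#' @param peaks `GRanges` of binding peaks.
#' @return `pairs` with a logical `bound` column, mixed pairs removed.
#' @export
classify_pairs_bound <- function(pairs, matches, peaks) {
  inpeak <- IRanges::overlapsAny(matches, peaks, ignore.strand = TRUE)
  a_in <- inpeak[pairs$index_a]
  b_in <- inpeak[pairs$index_b]
  keep <- a_in == b_in
  out <- pairs[keep, , drop = FALSE]
  out$bound <- a_in[keep]
  out
}

#' Hypergeometric enrichment of pair distances in the bound fraction
#'
#' For each observed distance d, tests whether bound pairs are
#' over-represented at d: with N pairs in total of which m lie at distance
#' d and n are bound, the upper-tail hypergeometric probability of seeing
#' at least the observed q bound pairs at d. Also reports the aggregate
#' bound fraction over the focal 12-50 bp band.
#'
#' @param pairs Data frame with `distance` and logical `bound` columns
#'   (see [classify_pairs_bound()]); must contain both bound and unbound
#'   pairs.
#' @param alpha Significance level for the `significant` flag.
#' @param band Integer range reported in aggregate (default `12:50`).
#' @return A list with `table` (per-distance counts, `pvalue`,
#'   `significant`) and `band_summary` (bound/total pair fractions inside
#'   the band).
#' @export
distance_enrichment <- function(pairs, alpha = 0.05, band = 12:50) {
  if (!nrow(pairs) || !any(pairs$bound) || all(pairs$bound))
    stop("need at least one bound and one unbound pair")
  N <- nrow(pairs)
  n <- sum(pairs$bound)
  ds <- sort(unique(pairs$distance))
  m <- vapply(ds, function(d) sum(pairs$distance == d), 0L)
  q <- vapply(ds, function(d) sum(pairs$bound & pairs$distance == d), 0L)
  p <- stats::phyper(q - 1, m, N - m, n, lower.tail = FALSE)
  tab <- data.frame(distance = ds, n_at_d = m, bound_at_d = q,
                    pvalue = p, significant = p < alpha)
  inband <- pairs$distance %in% band
  band_summary <- data.frame(
    band_lo = min(band), band_hi = max(band),
    pairs_in_band = sum(inband),
    bound_in_band = sum(pairs$bound & inband),
    frac_bound_pairs_in_band = if (n > 0) sum(pairs$bound & inband) / n else NA,
    frac_all_pairs_in_band = mean(inband))
  list(table = tab, band_summary = band_summary,
       n_pairs = N, n_bound = n)
}
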