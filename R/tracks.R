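#' Per-base signal tracks
#'
#' A `signal_track` stores one numeric value per base per chromosome —
#' sequencing tag counts (ChIP coverage, Tn5 cuts) or per-base ratios
#' (mappability, conservation, methylation). Count tracks carry a library
#' size (total tags) used for tags-per-10^7 normalization.
#'
#' @param values Named list of finite numeric vectors, one per chromosome;
#'   vector length is the chromosome length.
#' @param library_size Total tag count for count tracks; defaults to the sum
#'   of all values when `counts = TRUE`, `NULL` for ratio tracks.
#' @param counts Logical; is this a tag-count track?
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, library_size = NULL, counts = !is.null(library_size)) {
  stopifnot(is.list(values), !is.null(names(values)), all(nzchar(names(values))))
  for (v in values) {
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop("track values must be finite numerics")
  }
  if (counts && is.null(library_size)) library_size <- sum(vapply(values, sum, 0))
  if (counts && library_size <= 0) stop("library size must be > 0 for count tracks")
  structure(list(values = values, library_size = library_size),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$values), "chromosome(s),",
      sum(lengths(x$values)), "bases")
  if (!is.null(x$library_size)) cat(", library size", format(x$library_size))
  cat("\n")
  invisible(x)
}

#' Chromosome lengths of a track
#' @param track A `signal_track`.
#' @return Named integer vector.
#' @export
track_lengths <- function(track) {
  vapply(track$values, length, 1L)
}

#' Total signal in a track
#' @param track A `signal_track`.
#' @return Sum over all bases.
#' @export
track_total <- function(track) {
  sum(vapply(track$values, sum, 0))
}

# Window sums over one chromosome, 1-based closed coordinates, clipped.
.window_sums <- function(v, start, end) {
  cs <- c(0, cumsum(v))
  s <- pmax(start, 1L)
  e <- pmin(end, length(v))
  out <- numeric(length(start))
  ok <- e >= s
  out[ok] <- cs[e[ok] + 1L] - cs[s[ok]]
  out
}

#' Signal sums and means over intervals
#'
#' @param track A `signal_track` covering all chromosomes of `x`.
#' @param x A `GRanges`.
#' @return Numeric vector, one value per interval. `interval_means` divides
#'   by the number of bases actually covered (after clipping to chromosome
#'   ends).
#' @export
interval_sums <- function(track, x) {
  chroms <- as.character(GenomicRanges::seqnames(x))
  missing <- setdiff(unique(chroms), names(track$values))
  if (length(missing))
    stop("track does not cover chromosome(s): ", paste(missing, collapse = ", "))
  out <- numeric(length(x))
  st <- GenomicRanges::start(x)
  en <- GenomicRanges::end(x)
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    out[i] <- .window_sums(track$values[[ch]], st[i], en[i])
  }
  out
}

#' @rdname interval_sums
#' @export
interval_means <- function(track, x) {
  chroms <- as.character(GenomicRanges::seqnames(x))
  len <- track_lengths(track)[chroms]
  s <- pmax(GenomicRanges::start(x), 1L)
  e <- pmin(GenomicRanges::end(x), len)
  w <- pmax(e - s + 1, 0)
  sums <- interval_sums(track, x)
  ifelse(w > 0, sums / w, NA_real_)
}

#' Library normalization to tags per 10 million
#'
#' @param raw Raw tag count(s).
#' @param library_size Total tags in the library; must be positive.
#' @return `raw * 1e7 / library_size`.
#' @export
normalize_counts <- function(raw, library_size) {
  if (is.null(library_size) || length(library_size) != 1L || library_size <= 0)
    stop("`library_size` must be a single positive number")
  raw * 1e7 / library_size
}

#' Filter intervals by a per-base track statistic
#'
#' Keeps intervals whose per-base mean over the track satisfies the
#' comparison — e.g. mean mappability at least 0.8. The comparison is
#' inclusive on the kept side (`ge` keeps the boundary value).
#'
#' @param x A `GRanges`.
#' @param track A ratio `signal_track` (e.g. mappability).
#' @param stat Summary statistic; only `"mean"` is supported.
#' @param threshold Comparison value.
#' @param keep `"ge"` keeps mean >= threshold, `"lt"` keeps mean < threshold.
#' @return The retained subset of `x`.
#' @export
filter_by_track <- function(x, track, stat = "mean", threshold, keep = c("ge", "lt")) {
  stat <- match.arg(stat, "mean")
  keep <- match.arg(keep)
  if (length(x) == 0L) return(x)
  m <- interval_means(track, x)
  sel <- if (keep == "ge") m >= threshold else m < threshold
  sel[is.na(sel)] <- FALSE
  x[sel]
}

#' Binned signal around interval centers
#'
#' Sums track values in consecutive bins across a center-anchored window for
#' every interval, the layout used for coverage heatmaps. Count tracks are
#' library-normalized to tags per 10^7 first.
#'
#' @param x A `GRanges`.
#' @param track A `signal_track`.
#' @param window Window width in bases (centered on each interval midpoint).
#' @param bin Bin width; must divide `window`.
#' @return Numeric matrix `length(x)` rows by `window/bin` columns.
#' @export
annotate_window_signal <- function(x, track, window, bin = 25) {
  stopifnot(window > 0, bin > 0)
  if (window %% bin != 0) stop("`bin` must divide `window` evenly")
  nb <- window %/% bin
  # midpoint in 0-based coordinates, window [mid - window/2, mid + window/2)
  mid0 <- (GenomicRanges::start(x) - 1L + GenomicRanges::end(x)) %/% 2L
  w0 <- mid0 - window %/% 2L
  chroms <- as.character(GenomicRanges::seqnames(x))
  missing <- setdiff(unique(chroms), names(track$values))
  if (length(missing))
    stop("track does not cover chromosome(s): ", paste(missing, collapse = ", "))
  out <- matrix(0, nrow = length(x), ncol = nb)
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    v <- track$values[[ch]]
    for (j in seq_len(nb)) {
      bs <- w0[i] + (j - 1L) * bin + 1L   # back to 1-based
      out[i, j] <- .window_sums(v, bs, bs + bin - 1L)
    }
  }
  if (!is.null(track$library_size)) out <- normalize_counts(out, track$library_size)
  out
}

#' Fraction of reads in peaks (FRIP)
#'
#' @param reads A count `signal_track` with positive library size.
#' @param peaks A `GRanges` of called peaks (internally merged so shared
#'   bases are counted once).
#' @return Fraction of all tags falling inside peaks, in `[0, 1]`.
#' @export
frip <- function(reads, peaks) {
  if (is.null(reads$library_size) || reads$library_size <= 0)
    stop("`reads` must be a count track with positive library size")
  if (length(peaks) == 0L) return(0)
  merged <- merge_intervals(peaks, 0)
  sum(interval_sums(reads, merged)) / reads$library_size
}

#' Read / write per-base tracks as bedGraph
#'
#' `read_bedgraph` expands the interval-valued bedGraph (parsed with
#' [rtracklayer::import()]) into per-base vectors; uncovered bases are 0.
#' `write_bedgraph` run-length-compresses the track and omits zero runs.
#'
#' @param file Path to a bedGraph file.
#' @param chrom_lengths Named integer vector of chromosome lengths; defaults
#'   to the largest end coordinate seen per chromosome.
#' @param library_size Optional library size to attach (count tracks).
#' @return `read_bedgraph` returns a `signal_track`.
#' @export
read_bedgraph <- function(file, chrom_lengths = NULL, library_size = NULL) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(GenomicRanges::end(gr), chroms, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }
  st <- GenomicRanges::start(gr)
  wd <- GenomicRanges::width(gr)
  vals <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    i <- which(chroms == ch)
    if (length(i)) {
      idx <- sequence(wd[i]) + rep(st[i] - 1L, wd[i])
      v[idx] <- rep(gr$score[i], wd[i])
    }
    v
  })
  names(vals) <- names(chrom_lengths)
  signal_track(vals, library_size = library_size,
               counts = !is.null(library_size))
}

#' @rdname read_bedgraph
#' @param track A `signal_track` to write.
#' @export
write_bedgraph <- function(track, file) {
  chroms <- names(track$values)
  pieces <- lapply(chroms, function(ch) {
    r <- rle(track$values[[ch]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(factor(ch, levels = chroms),
                           IRanges::IRanges(s[keep], e[keep]),
                           score = r$values[keep])
  })
  gr <- do.call(c, c(pieces[!vapply(pieces, is.null, TRUE)], list()))
  if (is.null(gr)) gr <- GenomicRanges::GRanges(score = numeric())
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}
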