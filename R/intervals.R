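#' Build a GRanges from BED-style coordinates
#'
#' Interval sets are represented throughout the package as
#' [GenomicRanges::GRanges] objects (1-based, closed). File interchange uses
#' BED/bedGraph conventions (0-based, half-open); this helper converts
#' BED-style coordinates into the internal representation.
#'
#' @param chrom Character vector of sequence names.
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, 0-based exclusive end (`end > start`).
#' @param strand Strand vector (`"+"`, `"-"` or `"*"`).
#' @param seqlengths Optional named integer vector of chromosome lengths.
#' @param ... Further vectors stored as metadata columns.
#' @return A `GRanges` object.
#' @export
make_intervals <- function(chrom, start, end, strand = "*", seqlengths = NULL, ...) {
  stopifnot(all(end > start), all(start >= 0), all(nzchar(chrom)))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand,
    ...
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' Merge intervals closer than a gap
#'
#' Unions overlapping or book-ended intervals and additionally bridges
#' gaps strictly smaller than `min_gap` bases. Strand is ignored.
#'
#' @param x A `GRanges`.
#' @param min_gap Non-negative number of bases; intervals separated by fewer
#'   than `min_gap` uncovered bases are unioned. With `min_gap = 0` only
#'   overlapping or adjacent intervals are merged, which reproduces the runs
#'   of a per-base coverage mask.
#' @return A sorted, disjoint `GRanges`.
#' @export
merge_intervals <- function(x, min_gap = 0) {
  if (length(min_gap) != 1L || is.na(min_gap) || min_gap < 0)
    stop("`min_gap` must be a single non-negative number")
  GenomicRanges::reduce(x, min.gapwidth = max(as.integer(min_gap), 1L),
                        ignore.strand = TRUE)
}

#' Intersect two interval sets
#'
#' @param a,b `GRanges` objects.
#' @param mode `"overlap_regions"` returns the clipped intersections
#'   (bedtools-intersect semantics); `"a_with_any_overlap"` returns the
#'   members of `a` sharing at least one base with `b`, untouched.
#' @return A `GRanges`.
#' @export
intersect_intervals <- function(a, b, mode = c("overlap_regions", "a_with_any_overlap")) {
  mode <- match.arg(mode)
  if (mode == "overlap_regions") {
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  } else {
    IRanges::subsetByOverlaps(a, b, ignore.strand = TRUE)
  }
}

#' Symmetrically grow or shrink intervals
#'
#' Extends (`delta > 0`) or trims (`delta < 0`) every interval by `delta`
#' bases on each side. Results are clipped at position 0 and, where
#' `seqlengths` are known, at the chromosome end; intervals whose width would
#' become non-positive are dropped.
#'
#' @param x A `GRanges`.
#' @param delta Signed number of bases added to each side.
#' @return A `GRanges`.
#' @export
resize_intervals <- function(x, delta) {
  stopifnot(length(delta) == 1L, is.finite(delta))
  delta <- as.integer(delta)
  ns <- GenomicRanges::start(x) - delta
  ne <- GenomicRanges::end(x) + delta
  keep <- ne >= ns
  x <- x[keep]
  ns <- pmax(ns[keep], 1L)
  sl <- GenomeInfoDb::seqlengths(x)[as.character(GenomicRanges::seqnames(x))]
  ne <- ne[keep]
  ne <- ifelse(is.na(sl), ne, pmin(ne, sl))
  keep2 <- ne >= ns
  x <- x[keep2]
  IRanges::ranges(x) <- IRanges::IRanges(start = ns[keep2], end = ne[keep2])
  x
}

#' Refine broad accessible regions around focal insertion sites
#'
#' Narrow, focal insertion-site peaks are clipped to the broad accessible
#' regions they fall in, extended by 48 bp on each side, merged, and finally
#' reduced by 24 bp on each side. The net effect keeps a 24-bp margin around
#' each focal site while fusing sites whose extensions touch.
#'
#' @param small_peaks `GRanges` of focal (e.g. 12-bp) insertion-site peaks.
#' @param regions `GRanges` of broad accessible regions.
#' @return A `GRanges` of refined regions.
#' @export
refine_atac_regions <- function(small_peaks, regions) {
  x <- intersect_intervals(small_peaks, regions, mode = "overlap_regions")
  if (length(x) == 0L) return(x)
  x <- resize_intervals(x, 48L)
  x <- merge_intervals(x, 0)
  resize_intervals(x, -24L)
}

#' Remove intervals overlapping a blacklist
#'
#' Drops every member of `x` sharing at least one base with a blacklisted
#' region.
#'
#' @param x A `GRanges`.
#' @param blacklist A `GRanges` of excluded regions (may be empty).
#' @return The retained subset of `x`.
#' @export
subtract_blacklist <- function(x, blacklist) {
  if (length(blacklist) == 0L) return(x)
  x[!IRanges::overlapsAny(x, blacklist, ignore.strand = TRUE)]
}

#' Read / write BED files
#'
#' Thin wrappers around [rtracklayer::import()]/[rtracklayer::export()]
#' (BED is 0-based half-open on disk, 1-based closed as `GRanges`).
#' `write_bed_plus` writes BED6 plus arbitrary extra metadata columns as a
#' plain tab-separated file, the layout used for peak and cluster exports.
#'
#' @param file Path to a BED file.
#' @return `read_bed` returns a `GRanges`.
#' @export
read_bed <- function(file) {
  rtracklayer::import(file, format = "BED")
}

#' @rdname read_bed
#' @param x A `GRanges` to write.
#' @export
write_bed <- function(x, file) {
  rtracklayer::export(x, file, format = "BED")
  invisible(file)
}

#' @rdname read_bed
#' @param extra_cols Names of metadata columns appended after the six BED
#'   fields.
#' @export
write_bed_plus <- function(x, file, extra_cols = character()) {
  mc <- S4Vectors::mcols(x)
  nm <- if ("name" %in% names(mc)) as.character(mc$name) else rep(".", length(x))
  sc <- if ("score" %in% names(mc)) mc$score else rep(0, length(x))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    name = nm,
    score = sc,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(x))),
    stringsAsFactors = FALSE
  )
  for (cc in extra_cols) df[[cc]] <- mc[[cc]]
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
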