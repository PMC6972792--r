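# Per-base boolean-mask oracles for interval arithmetic, and small
# builders used across the test files. All coordinates here are 1-based
# closed (the GRanges convention); BED-style spec examples are converted
# where they appear.

mask_from_intervals <- function(starts, ends, L) {
  m <- logical(L)
  for (i in seq_along(starts)) m[starts[i]:ends[i]] <- TRUE
  m
}

runs_from_mask <- function(m) {
  r <- rle(m)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  keep <- r$values
  data.frame(start = s[keep], end = e[keep])
}

random_interval_set <- function(n, L, max_width = 200) {
  s <- sample.int(L - max_width, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + w - 1L))
}

gr_df <- function(x) {
  data.frame(start = GenomicRanges::start(x), end = GenomicRanges::end(x))
}

flat_track <- function(value, L, chrom = "chr1", counts = FALSE) {
  v <- stats::setNames(list(rep(value, L)), chrom)
  signal_track(v, counts = counts)
}

random_genome <- function(L, chroms = "chr1", gc = 0.5) {
  g <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""), "")
  stats::setNames(g, chroms)
}

# small synthetic configuration for fast determinism / pipeline tests
small_config <- function(seed = 1L) {
  synth_config(seed = seed,
               chrom_lengths = c(chr1 = 150000L, chr2 = 150000L),
               n_loci = 180L, n_pairs = 60L, n_genes = 16L, n_eqtl = 10L,
               n_lowmap = 4L, n_blacklist = 2L)
}
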