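# The benchmark synthetic experiment and its derived objects are expensive
# to build, so they are generated once per test session and shared.

.bench_cache <- new.env(parent = emptyenv())

bench_data <- function(seed = 42L) {
  key <- paste0("data_", seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- generate(benchmark_config(seed = seed))
  .bench_cache[[key]]
}

bench_peaks_stringent <- function(seed = 42L) {
  key <- paste0("peaks_", seed)
  if (is.null(.bench_cache[[key]])) {
    d <- bench_data(seed)
    .bench_cache[[key]] <- call_peaks_factor(d$tracks$chip,
                                             d$tracks$chip_control,
                                             stringent = TRUE)
  }
  .bench_cache[[key]]
}

bench_filtered_matches <- function(seed = 42L) {
  key <- paste0("filtered_", seed)
  if (is.null(.bench_cache[[key]])) {
    d <- bench_data(seed)
    m <- scan_genome(d$pwm, d$genome)
    .bench_cache[[key]] <- mappability_filter(m, d$tracks$mappability,
                                              d$blacklist)
  }
  .bench_cache[[key]]
}

bench_run <- function(seed = 42L) {
  key <- paste0("run_", seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- suppressWarnings(
      run_pipeline(bench_data(seed), pred_seed = seed))
  .bench_cache[[key]]
}

# adjusted Rand index between two labelings (standard contingency form)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
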