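# The synthetic-experiment generator: validation, determinism and the
# statistical invariants the emulated structure must satisfy.

test_that("configuration validates and benchmark defaults are frozen", {
  expect_silent(validate_config(benchmark_config()))
  expect_equal(benchmark_config(seed = 3), benchmark_config(seed = 3))
  cfg <- benchmark_config()
  expect_equal(sum(cfg$class_props), 1)
  expect_equal(cfg$n_loci + cfg$n_pairs, 2000L)
  expect_error(synth_config(class_props = c(denovo = 0.5, preacc = 0.5,
                                            unbound = 0.5, lost = 0.5)),
               "class_props")
  expect_error(synth_config(meth_fraction = 2), "meth_fraction")
  expect_error(synth_config(bogus_field = 1), "unknown")
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate(small_config(seed = 5))
  b <- generate(small_config(seed = 5))
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth$motifs, b$truth$motifs)
  expect_identical(a$tracks$atac_pre$values, b$tracks$atac_pre$values)
  expect_identical(a$genes, b$genes)
  c2 <- generate(small_config(seed = 6))
  expect_false(identical(a$genome, c2$genome))
})

test_that("planted truth is internally consistent", {
  d <- generate(small_config(seed = 2))
  m <- d$truth$motifs
  # every planted word sits in the genome at its coordinates
  idx <- sample.int(nrow(m), 40)
  for (i in idx) {
    s <- substr(d$genome[[m$chrom[i]]], m$start[i], m$end[i])
    if (m$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(s, m$word[i])
  }
  # all planted scores reach the scan threshold
  expect_true(all(m$score >= d$pwm$threshold))
  # lost sites are never bound; remodeled = de novo & bound
  expect_true(all(!m$bound[m$class == "lost"]))
  expect_identical(m$remodeled, m$class == "denovo" & m$bound)
  # pair distances respect the configured range
  expect_true(all(d$truth$pairs$distance >= 12 &
                    d$truth$pairs$distance <= 150))
})

test_that("bound fraction matches the generative model expectation", {
  d <- generate(benchmark_config(seed = 42))
  m <- d$truth$motifs
  expected <- sum(m$bound_prob)
  # paired members share one binding event, doubling their variance term
  paired <- !is.na(m$pair_id)
  v <- sum(m$bound_prob[!paired] * (1 - m$bound_prob[!paired])) +
    4 * sum(unique(data.frame(id = m$pair_id[paired],
                              p = m$bound_prob[paired]))$p *
              (1 - unique(data.frame(id = m$pair_id[paired],
                                     p = m$bound_prob[paired]))$p))
  expect_lt(abs(sum(m$bound) - expected), 3 * sqrt(v) + 3)
})

test_that("remodeling magnitude at de novo sites matches the configuration", {
  d <- bench_data()
  cfg <- d$config
  m <- d$truth$motifs
  sites <- function(rows) GenomicRanges::GRanges(
    m$chrom[rows], IRanges::IRanges(m$start[rows], m$end[rows]))
  # paired members have overlapping accessibility windows, so the clean
  # single-site expectation is checked on unpaired motifs
  unpaired <- is.na(m$pair_id)
  cm_rem <- peak_count_matrix(sites(which(m$remodeled & unpaired)),
                              d$tracks$atac_pre, d$tracks$atac_post)
  cm_un <- peak_count_matrix(sites(which(m$class == "unbound" & !m$bound &
                                           unpaired)),
                             d$tracks$atac_pre, d$tracks$atac_post)
  ratio_rem <- mean(cm_rem[, "post"]) / mean(cm_rem[, "pre"]) /
    (mean(cm_un[, "post"]) / mean(cm_un[, "pre"]))
  # expected fold: open window over closed window, with the footprint dip
  # carved out of the motif span (library scaling cancels against the
  # unbound comparator)
  open_cuts <- cfg$atac_bg * 300 + cfg$atac_amp * 300 -
    (cfg$atac_bg + cfg$atac_amp) * 12 * (1 - cfg$footprint_dip)
  closed_cuts <- cfg$atac_bg * 300
  expected <- open_cuts / closed_cuts
  expect_equal(ratio_rem, expected, tolerance = 0.1)
})

test_that("methylation suppresses binding signal by the configured factor", {
  cfg <- synth_config(seed = 8, chrom_lengths = c(chr1 = 900000L),
                      n_loci = 2000L, n_pairs = 0L, cg_fraction = 0.5,
                      min_locus_separation = 420L,
                      n_genes = 10L, n_eqtl = 5L)
  d <- generate(cfg)
  m <- d$truth$motifs
  win <- function(rows) GenomicRanges::GRanges(
    m$chrom[rows], IRanges::IRanges(pmax(m$center[rows] - 100, 1),
                                    m$center[rows] + 100))
  meth <- which(m$methylated)
  unmeth <- which(m$cpg_core & !m$methylated)
  cov_m <- mean(interval_sums(d$tracks$chip, win(meth)))
  cov_u <- mean(interval_sums(d$tracks$chip, win(unmeth)))
  # scores are drawn identically for the two groups, so mean coverage
  # scales with the binding-probability suppression factor
  expect_equal(cov_m / cov_u, cfg$meth_suppression, tolerance = 0.2)
})

test_that("a motif-free configuration yields background only", {
  cfg <- synth_config(seed = 4, chrom_lengths = c(chr1 = 120000L),
                      n_loci = 2L, n_pairs = 0L, n_genes = 6L, n_eqtl = 3L,
                      n_lowmap = 2L, n_blacklist = 1L)
  d <- generate(cfg)
  hits <- scan_genome(d$pwm, d$genome)
  # both planted sites are found ...
  idx <- match_truth(hits, d$truth$motifs)
  expect_true(all(1:2 %in% idx[!is.na(idx)]))
  # ... and everything else matches the chance rate of a random genome
  set.seed(91)
  bg_hits <- scan_genome(d$pwm, random_genome(120000, gc = 0.41))
  expect_lt(abs(length(hits) - 2 - length(bg_hits)),
            4 * sqrt(length(hits) + length(bg_hits)) + 10)
})

test_that("synthetic data round-trips through standard formats", {
  dir <- withr::local_tempdir()
  d <- generate(small_config(seed = 3))
  paths <- write_synth_data(d, dir)
  g <- Biostrings::readDNAStringSet(paths["genome"])
  expect_equal(as.character(g[["chr1"]]), d$genome[["chr1"]])
  pwms <- read_pwm(paths["pwm"])
  expect_equal(pwms$PU1$probs, d$pwm$probs, tolerance = 1e-7)
  tr <- read_bedgraph(paths["atac_pre"],
                      chrom_lengths = track_lengths(d$tracks$atac_pre))
  expect_equal(tr$values, d$tracks$atac_pre$values)
  genes <- read_gene_table(paths["genes"])
  expect_equal(genes$gene, d$genes$gene)
  bl <- read_bed(paths["blacklist"])
  expect_equal(gr_df(bl), gr_df(d$blacklist))
})
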