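#' Run the full binding-site selection analysis
#'
#' Orchestrates the complete workflow on a synthetic (or pre-generated)
#' experiment: simulate, scan, motif filtering, peak calling (ChIP factor
#' mode standard/stringent, ATAC region mode, differential regions),
#' accessibility clustering, footprints, homotypic pairs and motif-class
#' network, peak-to-gene assignment with expression tests, and logistic
#' binding prediction. Stages run in dependency order; every stage is
#' logged in a manifest with its input/output sizes. Re-running with the
#' same configuration reproduces identical results (all randomness derives
#' from the config seed and `pred_seed`).
#'
#' @param data A `synth_data` object, or `NULL` to generate one from
#'   `config`.
#' @param config A `synth_config` used when `data` is NULL.
#' @param K Number of accessibility clusters (default 14).
#' @param pred_seed Seed for the prediction train/test split and cluster
#'   restarts.
#' @param n_splits Repeated random halves averaged in the predictor-set
#'   comparison.
#' @param verbose Print stage progress.
#' @return A list of class `pioneerscan_run` with one element per stage
#'   plus `manifest` (data frame: stage, n_in, n_out, status).
#' @export
run_pipeline <- function(data = NULL, config = benchmark_config(), K = 14,
                         pred_seed = 1L, n_splits = 5L, verbose = FALSE) {
  manifest <- list()
  log_stage <- function(stage, n_in, n_out) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, status = "ok",
      stringsAsFactors = FALSE)
    if (verbose) message(sprintf("[%s] in=%s out=%s", stage, n_in, n_out))
  }

  ## 1. simulate
  if (is.null(data)) data <- generate(config)
  cfg <- data$config
  log_stage("simulate", NA, nrow(data$truth$motifs))

  ## 2. scan
  matches <- scan_genome(data$pwm, data$genome)
  partner_matches <- lapply(data$partner_pwms, scan_genome,
                            genome = data$genome)
  log_stage("scan", sum(nchar(data$genome)), length(matches))

  ## 3. motif filtering
  filtered <- mappability_filter(matches, data$tracks$mappability,
                                 data$blacklist)
  filtered <- no_signal_motifs(filtered, list(data$tracks$chip))
  log_stage("motif_filter", length(matches), length(filtered))

  ## 4. peak calling
  peaks_std <- call_peaks_factor(data$tracks$chip, data$tracks$chip_control)
  peaks_str <- call_peaks_factor(data$tracks$chip, data$tracks$chip_control,
                                 stringent = TRUE)
  atac_regions_pre <- call_peaks_region(data$tracks$atac_pre)
  atac_regions_post <- call_peaks_region(data$tracks$atac_post)
  atac_all <- merge_intervals(c(atac_regions_pre, atac_regions_post), 0)
  diff_atac <- differential_regions(list(data$tracks$atac_pre),
                                    list(data$tracks$atac_post), atac_all)
  log_stage("callpeaks", NA, length(peaks_std))

  ## 5. accessibility clustering
  cmat <- peak_count_matrix(peaks_str, data$tracks$atac_pre,
                            data$tracks$atac_post)
  clusters <- if (length(peaks_str) >= K)
    cluster_peaks(cmat, K = K, seed = pred_seed) else NULL
  log_stage("cluster", length(peaks_str),
            if (is.null(clusters)) 0L else clusters$K)

  ## 6. footprint
  bound_matches <- intersect_intervals(filtered, peaks_str,
                                       mode = "a_with_any_overlap")
  footprint <- if (length(bound_matches))
    footprint_profile(bound_matches, data$tracks$atac_post) else NULL
  log_stage("footprint", length(bound_matches),
            if (is.null(footprint)) 0L else nrow(footprint))

  ## 7. pairs and network
  pairs <- enumerate_pairs(filtered)
  pairs <- classify_pairs_bound(pairs, filtered, peaks_str)
  enrichment <- if (nrow(pairs) && any(pairs$bound) && !all(pairs$bound))
    distance_enrichment(pairs) else NULL
  pcm <- peak_class_matrix(peaks_str, filtered, partner_matches)
  network <- if (length(peaks_str)) build_network(pcm) else NULL
  log_stage("pairs_network", nrow(pairs),
            if (is.null(enrichment)) 0L else sum(enrichment$table$significant))

  ## 8. gene assignment and expression
  domains <- build_domains(data$genes, chrom_lengths = cfg$chrom_lengths)
  assignment <- assign_regions(peaks_str, data$genes, domains, data$eqtls)
  expr_test <- NULL
  if (!is.null(clusters)) {
    assignment$cluster <- clusters$assignment[assignment$region_index]
    expr_test <- cluster_expression_test(
      assignment[!is.na(assignment$gene), , drop = FALSE],
      data$genes[, c("gene", "control", "induced")])
  }
  log_stage("assign", length(peaks_str), sum(!is.na(assignment$gene)))

  ## 9. binding prediction
  features <- assemble_features(filtered, data$tracks$conservation,
                                partner_matches, data$tracks$atac_pre,
                                data$tracks$atac_post, peaks_str)
  sets <- default_predictor_sets(names(partner_matches))
  prediction <- compare_predictor_sets(features, sets, split_seed = pred_seed,
                                       n_splits = n_splits)
  log_stage("predict", nrow(features), nrow(prediction))

  structure(list(
    data = data, matches = matches, partner_matches = partner_matches,
    filtered = filtered, peaks_standard = peaks_std,
    peaks_stringent = peaks_str, atac_regions_pre = atac_regions_pre,
    atac_regions_post = atac_regions_post, diff_atac = diff_atac,
    count_matrix = cmat, clusters = clusters, footprint = footprint,
    pairs = pairs, enrichment = enrichment, class_matrix = pcm,
    network = network, domains = domains, assignment = assignment,
    expression_test = expr_test, features = features,
    prediction = prediction,
    manifest = do.call(rbind, manifest)), class = "pioneerscan_run")
}

#' @export
print.pioneerscan_run <- function(x, ...) {
  cat("pioneerscan_run\n")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' Match scanned motifs to planted ground truth
#'
#' Joins scan results to the generator's truth table by chromosome, start
#' and strand.
#'
#' @param matches `GRanges` of scanned matches.
#' @param truth_motifs Truth table from a `synth_data` object.
#' @return Integer vector: row of `truth_motifs` for each match (`NA` for
#'   background matches not planted).
#' @export
match_truth <- function(matches, truth_motifs) {
  key <- function(ch, st, sd) paste(ch, st, sd, sep = ":")
  mk <- key(as.character(GenomicRanges::seqnames(matches)),
            GenomicRanges::start(matches),
            as.character(GenomicRanges::strand(matches)))
  tk <- key(truth_motifs$chrom, truth_motifs$start, truth_motifs$strand)
  match(mk, tk)
}
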