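#' Surrogate PWMs for the induced factor and its partner classes
#'
#' `surrogate_pu1_pwm` builds a width-12 ETS-family surrogate with the
#' invariant GGAA core at columns 6-9 (consensus `AAAGAGGAAGTG`), a
#' stand-in for the published consensus matrix, which is an external input
#' at full scale. `surrogate_partner_pwms` builds short surrogates for the
#' co-associated classes (RUNX, GATA, Ebox).
#'
#' @param threshold Log-odds scan threshold (default 6, natural log).
#' @return A `pwm`, or a named list of `pwm`s.
#' @export
surrogate_pu1_pwm <- function(threshold = 6) {
  cons <- strsplit("AAAGAGGAAGTG", "")[[1]]
  p_cons <- c(0.40, 0.40, 0.70, 0.70, 0.70, 0.94, 0.94, 0.94, 0.94,
              0.70, 0.70, 0.40)
  probs <- .consensus_probs(cons, p_cons)
  pwm(probs, name = "PU1", threshold = threshold, core_offset = 6L)
}

#' @rdname surrogate_pu1_pwm
#' @export
surrogate_partner_pwms <- function(threshold = 4) {
  build <- function(name, cons, p) {
    pwm(.consensus_probs(strsplit(cons, "")[[1]], rep(p, nchar(cons))),
        name = name, threshold = threshold)
  }
  list(RUNX = build("RUNX", "TGTGGTTT", 0.85),
       GATA = build("GATA", "AGATAAGA", 0.85),
       EBOX = build("EBOX", "CACCTG", 0.88))
}

# probability matrix with p at the consensus base, rest split evenly
.consensus_probs <- function(cons, p_cons) {
  bases <- c("A", "C", "G", "T")
  t(vapply(seq_along(cons), function(i) {
    row <- rep((1 - p_cons[i]) / 3, 4)
    row[match(cons[i], bases)] <- p_cons[i]
    row
  }, numeric(4)))
}

#' Synthetic-experiment configuration
#'
#' All parameters of the two-condition (factor-induced versus control)
#' synthetic experiment. `benchmark_config()` returns the frozen default
#' configuration used throughout the test suite: a 2-Mb genome on two
#' chromosomes, 2,000 planted motifs (1,500 loci of which 500 carry a
#' homotypic partner), site-class proportions 25% de-novo-remodeled / 15%
#' pre-accessible / 55% unbound / 5% lost-accessibility, and cut libraries
#' of about 10^6.
#'
#' @param seed Integer seed fixing every draw.
#' @param ... Overrides for individual fields (see the returned list).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = c(chr1 = 1000000L, chr2 = 1000000L),
    gc = 0.41,
    n_loci = 1200L,            # planted motif loci
    n_pairs = 800L,            # loci additionally carrying a homotypic partner
    min_locus_separation = 400L,
    class_props = c(denovo = 0.25, preacc = 0.15, unbound = 0.55, lost = 0.05),
    # truncated-normal log-odds score targets per class
    score_mean = c(denovo = 9.5, preacc = 8, unbound = 7.5, lost = 8),
    score_sd = 1,
    score_range = c(6.3, 11.5),
    cpg_score_max = 9.7,
    # binding model: logistic in score and pre-accessibility
    bind_b0 = -9, bind_b_score = 1, bind_b_access = 3.5,
    # homotypic pair spacings; binding at paired loci is a pair-level
    # event dominated by spacing-dependent cooperativity
    pair_band = c(15L, 45L),
    pair_band_frac = 0.45,
    pair_dist_range = c(12L, 150L),
    pair_bound_in_band = 0.95,
    pair_bound_out_band = 0.05,
    pair_b_access = 1.5,
    # heterotypic partner co-planting
    partner_rate_bound_low = 0.6,   # bound site, below-median score
    partner_rate_bound_high = 0.3,
    partner_rate_unbound = 0.15,
    partner_offset_range = c(25L, 90L),
    # CpG-core methylation
    cg_fraction = 0.15,
    meth_fraction = 0.5,
    meth_suppression = 0.25,
    # tracks
    atac_bg = 0.3, atac_amp = 3, atac_halfwidth = 150L,
    footprint_dip = 0.4,
    chip_bg = 1e-4, chip_amp = 1, chip_halfwidth = 100L,
    # annotation tracks
    n_lowmap = 15L, lowmap_width = c(500L, 3000L), lowmap_value = 0.3,
    n_blacklist = 6L, blacklist_width = c(1000L, 3000L),
    cons_shape = c(2, 20), cons_boost = 0.25, cons_frac = 0.6,
    # genes and expression
    n_genes = 80L, expressed_frac = 0.85,
    expr_meanlog = 3, expr_sdlog = 1,
    expr_fold = 2, expr_noise_sdlog = 0.15,
    n_eqtl = 60L,
    pwm_threshold = 6)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @export
benchmark_config <- function(seed = 1L) synth_config(seed = seed)

#' Validate a synthetic-experiment configuration
#'
#' @param cfg A config list.
#' @return Invisibly `TRUE`; otherwise an error listing the failing fields.
#' @export
validate_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(abs(sum(cfg$class_props) - 1) < 1e-9, "class_props must sum to 1")
  chk(all(cfg$class_props >= 0), "class_props must be non-negative")
  for (f in c("pair_band_frac", "cg_fraction", "meth_fraction",
              "meth_suppression", "expressed_frac", "footprint_dip",
              "partner_rate_bound_low", "partner_rate_bound_high",
              "partner_rate_unbound"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste(f, "must be in [0, 1]"))
  chk(cfg$gc > 0 && cfg$gc < 1, "gc must be in (0, 1)")
  chk(all(cfg$chrom_lengths > 0), "chrom_lengths must be positive")
  chk(cfg$n_pairs <= cfg$n_loci, "n_pairs must not exceed n_loci")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed must be a scalar")
  if (length(bad)) stop("invalid synth_config: ", paste(bad, collapse = "; "))
  invisible(TRUE)
}

# hill-climb a word (integer codes) toward a target log-odds score;
# `fixed` marks columns that must not be mutated
.word_for_score <- function(lo, target, fixed, start_codes, max_iter = 250) {
  w <- nrow(lo)
  codes <- start_codes
  sc <- sum(lo[cbind(seq_len(w), codes)])
  free <- which(!fixed)
  if (!length(free)) return(codes)
  for (i in seq_len(max_iter)) {
    if (abs(sc - target) <= 0.15) break
    j <- free[sample.int(length(free), 1)]
    b <- sample.int(4, 1)
    if (b == codes[j]) next
    new_sc <- sc - lo[j, codes[j]] + lo[j, b]
    if (abs(new_sc - target) < abs(sc - target)) {
      codes[j] <- b
      sc <- new_sc
    }
  }
  codes
}

# sample k integer positions in [lo, hi] pairwise >= sep apart, sorted
.spaced_positions <- function(k, lo, hi, sep) {
  span <- hi - lo - (k - 1) * sep
  if (span < k) stop("chromosome too short for requested site density")
  base <- sort(sample.int(span, k))
  lo + base + (seq_len(k) - 1L) * sep
}

#' Generate a synthetic two-condition experiment
#'
#' Builds, from a single seed, a background genome with planted motif
#' instances, homotypic pairs and heterotypic partner motifs; pre- and
#' post-induction Tn5 cut tracks with class-dependent remodeling and
#' footprint-shaped cut depletion at bound sites; ChIP tag tracks for the
#' induced factor and a control; mappability, blacklist, conservation and
#' CpG-methylation annotation tracks; gene models with expression coupled
#' to remodeled regulatory domains; an eQTL table; and ground-truth tables
#' for every planted feature.
#'
#' @param config A `synth_config` (default [benchmark_config()]).
#' @return A list of class `synth_data` with elements `genome`, `pwm`,
#'   `partner_pwms`, `tracks` (atac_pre, atac_post, chip, chip_control,
#'   mappability, conservation, methylation), `blacklist`, `genes`,
#'   `eqtls`, `truth` (`motifs`, `pairs`, `partners`, `genes`) and
#'   `config`.
#' @export
generate <- function(config = benchmark_config()) {
  validate_config(config)
  with_local_seed(config$seed, .generate_impl(config))
}

.generate_impl <- function(cfg) {
  bases <- c("A", "C", "G", "T")
  base_probs <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  chroms <- names(cfg$chrom_lengths)
  motif <- surrogate_pu1_pwm(threshold = cfg$pwm_threshold)
  partners <- surrogate_partner_pwms()
  lo <- pwm_logodds(motif)[, 1:4]
  w <- pwm_width(motif)
  co <- motif$core_offset
  cons_codes <- match(strsplit(pwm_consensus(motif), "")[[1]], bases)

  ## --- background genome ------------------------------------------------
  genome_chars <- lapply(cfg$chrom_lengths, function(n)
    sample(bases, n, replace = TRUE, prob = base_probs))

  ## --- motif loci -------------------------------------------------------
  n_per_chrom <- round(cfg$n_loci * cfg$chrom_lengths / sum(cfg$chrom_lengths))
  n_per_chrom[1] <- cfg$n_loci - sum(n_per_chrom[-1])
  locus <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    pos <- .spaced_positions(n_per_chrom[ci], 1000L,
                             cfg$chrom_lengths[ci] - 1000L,
                             cfg$min_locus_separation)
    data.frame(chrom = chroms[ci], start = pos, stringsAsFactors = FALSE)
  }))
  n_loci <- nrow(locus)
  locus$class <- sample(names(cfg$class_props), n_loci, replace = TRUE,
                        prob = cfg$class_props)
  locus$strand <- sample(c("+", "-"), n_loci, replace = TRUE)
  locus$is_pair <- seq_len(n_loci) %in% sample.int(n_loci, cfg$n_pairs)
  # CpG cores are planted at unpaired loci only: paired motifs are excluded
  # from the methylation analysis anyway (the signal could derive from the
  # unmethylated neighbor)
  locus$cpg <- stats::runif(n_loci) < cfg$cg_fraction & !locus$is_pair

  # homotypic partner rows
  band <- cfg$pair_band
  out_band <- setdiff(seq(cfg$pair_dist_range[1], cfg$pair_dist_range[2]),
                      seq(band[1], band[2]))
  pair_rows <- which(locus$is_pair)
  pair_d <- ifelse(stats::runif(length(pair_rows)) < cfg$pair_band_frac,
                   sample(seq(band[1], band[2]), length(pair_rows), replace = TRUE),
                   sample(out_band, length(pair_rows), replace = TRUE))
  partner_df <- data.frame(
    chrom = locus$chrom[pair_rows],
    start = locus$start[pair_rows] + pair_d,
    class = locus$class[pair_rows],
    strand = sample(c("+", "-"), length(pair_rows), replace = TRUE),
    is_pair = rep(TRUE, length(pair_rows)),
    cpg = rep(FALSE, length(pair_rows)),
    pair_id = seq_along(pair_rows),
    pair_distance = pair_d,
    stringsAsFactors = FALSE)
  motifs <- data.frame(
    chrom = locus$chrom, start = locus$start, class = locus$class,
    strand = locus$strand, is_pair = locus$is_pair, cpg = locus$cpg,
    pair_id = ifelse(locus$is_pair,
                     match(seq_len(n_loci), pair_rows), NA_integer_),
    pair_distance = NA_integer_, stringsAsFactors = FALSE)
  motifs$pair_distance[pair_rows] <- pair_d
  motifs <- rbind(motifs, partner_df[, names(motifs)])
  n_mot <- nrow(motifs)

  ## --- motif sequences --------------------------------------------------
  tgt <- stats::rnorm(n_mot, cfg$score_mean[motifs$class], cfg$score_sd)
  tgt <- pmin(pmax(tgt, cfg$score_range[1]), cfg$score_range[2])
  tgt[motifs$cpg] <- pmin(tgt[motifs$cpg], cfg$cpg_score_max)
  words <- character(n_mot)
  score_realized <- numeric(n_mot)
  for (i in seq_len(n_mot)) {
    start_codes <- cons_codes
    fixed <- rep(FALSE, w)
    if (motifs$cpg[i]) {
      start_codes[co - 1L] <- 2L           # C immediately 5' of the core
      fixed[(co - 1L):(co + 3L)] <- TRUE   # hold CGGAA intact
    }
    codes <- .word_for_score(lo, tgt[i], fixed, start_codes)
    words[i] <- paste(bases[codes], collapse = "")
    score_realized[i] <- sum(lo[cbind(seq_len(w), codes)])
  }
  motifs$score <- score_realized
  motifs$end <- motifs$start + w - 1L

  # embed (reverse complement for minus-strand plants)
  for (i in seq_len(n_mot)) {
    seq_w <- words[i]
    if (motifs$strand[i] == "-")
      seq_w <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq_w)))
    genome_chars[[motifs$chrom[i]]][motifs$start[i]:motifs$end[i]] <-
      strsplit(seq_w, "")[[1]]
  }
  motifs$word <- words
  motifs$cpg_core <- substr(words, co - 1L, co + 3L) == "CGGAA"

  ## --- binding truth ----------------------------------------------------
  # Unpaired motifs: logistic in score and pre-accessibility. Paired loci:
  # a pair-level binding event whose probability depends on the spacing
  # (cooperative binding at preferred spacings), shared by both members.
  motifs$pre_open <- motifs$class %in% c("preacc", "lost")
  eta <- cfg$bind_b0 + cfg$bind_b_score * motifs$score +
    cfg$bind_b_access * as.numeric(motifs$pre_open)
  p_bound <- stats::plogis(eta)
  is_paired <- !is.na(motifs$pair_id)
  pair_in_band_by_id <- pair_d >= band[1] & pair_d <= band[2]
  pair_pre_open_by_id <- locus$class[pair_rows] %in% c("preacc", "lost")
  p_pair_by_id <- stats::plogis(
    stats::qlogis(ifelse(pair_in_band_by_id,
                         cfg$pair_bound_in_band, cfg$pair_bound_out_band)) +
      cfg$pair_b_access * as.numeric(pair_pre_open_by_id))
  pair_event <- stats::runif(cfg$n_pairs) < p_pair_by_id
  p_bound[is_paired] <- p_pair_by_id[motifs$pair_id[is_paired]]
  p_bound[motifs$class == "lost"] <- 0
  motifs$methylated <- motifs$cpg_core & stats::runif(n_mot) < cfg$meth_fraction
  p_bound[motifs$methylated] <- p_bound[motifs$methylated] * cfg$meth_suppression
  motifs$bound_prob <- p_bound
  bound <- stats::runif(n_mot) < p_bound
  # paired members share the pair-level event (methylated members may still
  # escape binding, and lost-class pairs stay unbound)
  shared <- pair_event[motifs$pair_id[is_paired]]
  bound[is_paired] <- shared & !(motifs$class[is_paired] == "lost")
  meth_paired <- is_paired & motifs$methylated
  bound[meth_paired] <- bound[meth_paired] &
    stats::runif(sum(meth_paired)) < cfg$meth_suppression
  motifs$bound <- bound
  motifs$post_open <- (motifs$pre_open & motifs$class != "lost") |
    (motifs$class == "denovo" & motifs$bound)
  motifs$remodeled <- motifs$class == "denovo" & motifs$bound
  motifs$center <- (motifs$start + motifs$end) %/% 2L

  ## --- heterotypic partner motifs ---------------------------------------
  med_score <- stats::median(motifs$score)
  p_partner <- ifelse(motifs$bound,
                      ifelse(motifs$score < med_score,
                             cfg$partner_rate_bound_low,
                             cfg$partner_rate_bound_high),
                      cfg$partner_rate_unbound)
  # co-plant only at unpaired loci so partner words never overwrite a
  # planted homotypic pair member
  has_partner <- stats::runif(n_mot) < p_partner & !motifs$is_pair
  partner_rows <- list()
  for (i in which(has_partner)) {
    cls <- sample(names(partners), 1)
    pw <- partners[[cls]]
    pwidth <- pwm_width(pw)
    off <- sample(seq(cfg$partner_offset_range[1],
                      cfg$partner_offset_range[2]), 1)
    pstart <- motifs$center[i] - off - pwidth + 1L
    if (pstart < 1) next
    pcodes <- vapply(seq_len(pwidth), function(j)
      sample.int(4, 1, prob = pw$probs[j, ]), 1L)
    pword <- paste(bases[pcodes], collapse = "")
    genome_chars[[motifs$chrom[i]]][pstart:(pstart + pwidth - 1L)] <-
      strsplit(pword, "")[[1]]
    partner_rows[[length(partner_rows) + 1L]] <- data.frame(
      chrom = motifs$chrom[i], start = pstart, end = pstart + pwidth - 1L,
      class = cls, anchor_row = i, stringsAsFactors = FALSE)
  }
  partner_truth <- if (length(partner_rows)) do.call(rbind, partner_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               class = character(), anchor_row = integer())

  genome <- vapply(genome_chars, paste, "", collapse = "")

  ## --- accessibility (cut) tracks ---------------------------------------
  add_window <- function(rate, rows, halfwidth, amp) {
    for (i in rows) {
      ch <- motifs$chrom[i]
      s <- max(1L, motifs$center[i] - halfwidth)
      e <- min(length(rate[[ch]]), motifs$center[i] + halfwidth)
      rate[[ch]][s:e] <- rate[[ch]][s:e] + amp
    }
    rate
  }
  dip_window <- function(rate, rows, dip) {
    for (i in rows) {
      ch <- motifs$chrom[i]
      rate[[ch]][motifs$start[i]:motifs$end[i]] <-
        rate[[ch]][motifs$start[i]:motifs$end[i]] * dip
    }
    rate
  }
  blank_rate <- lapply(cfg$chrom_lengths, function(n) rep(cfg$atac_bg, n))
  pre_rate <- add_window(blank_rate, which(motifs$pre_open),
                         cfg$atac_halfwidth, cfg$atac_amp)
  post_rate <- add_window(blank_rate, which(motifs$post_open),
                          cfg$atac_halfwidth, cfg$atac_amp)
  post_rate <- dip_window(post_rate, which(motifs$bound), cfg$footprint_dip)
  draw_track <- function(rate) {
    vals <- lapply(rate, function(r) as.numeric(stats::rpois(length(r), r)))
    signal_track(vals, counts = TRUE)
  }
  atac_pre <- draw_track(pre_rate)
  atac_post <- draw_track(post_rate)

  ## --- ChIP tracks -------------------------------------------------------
  chip_rate <- lapply(cfg$chrom_lengths, function(n) rep(cfg$chip_bg, n))
  chip_rate <- add_window(chip_rate, which(motifs$bound),
                          cfg$chip_halfwidth, cfg$chip_amp)
  chip <- draw_track(chip_rate)
  chip_control <- draw_track(lapply(cfg$chrom_lengths,
                                    function(n) rep(cfg$chip_bg, n)))

  ## --- annotation tracks -------------------------------------------------
  rand_intervals <- function(n, width_range) {
    ch <- sample(chroms, n, replace = TRUE)
    wd <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
    st <- vapply(seq_len(n), function(i)
      sample.int(cfg$chrom_lengths[[ch[i]]] - wd[i], 1), 1L)
    GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = wd))
  }
  lowmap <- rand_intervals(cfg$n_lowmap, cfg$lowmap_width)
  mapp_vals <- lapply(cfg$chrom_lengths, function(n) rep(1, n))
  for (i in seq_along(lowmap)) {
    ch <- as.character(GenomicRanges::seqnames(lowmap))[i]
    mapp_vals[[ch]][GenomicRanges::start(lowmap)[i]:GenomicRanges::end(lowmap)[i]] <-
      cfg$lowmap_value
  }
  mappability <- signal_track(mapp_vals, counts = FALSE)
  blacklist <- GenomicRanges::reduce(rand_intervals(cfg$n_blacklist,
                                                    cfg$blacklist_width))
  cons_vals <- lapply(cfg$chrom_lengths, function(n)
    stats::rbeta(n, cfg$cons_shape[1], cfg$cons_shape[2]))
  # only a fraction of bound motifs are conserved, so conservation is
  # informative but weaker than accessibility
  conserved <- motifs$bound & stats::runif(n_mot) < cfg$cons_frac
  for (i in which(conserved)) {
    ch <- motifs$chrom[i]
    s <- max(1L, motifs$start[i] - 10L)
    e <- min(length(cons_vals[[ch]]), motifs$end[i] + 10L)
    cons_vals[[ch]][s:e] <- pmin(cons_vals[[ch]][s:e] + cfg$cons_boost, 1)
  }
  conservation <- signal_track(cons_vals, counts = FALSE)
  meth_vals <- lapply(cfg$chrom_lengths, function(n) rep(0, n))
  for (i in which(motifs$cpg_core)) {
    ch <- motifs$chrom[i]
    # CpG position in reference coordinates
    pos <- if (motifs$strand[i] == "+") motifs$start[i] + co - 2L else
      motifs$end[i] - co + 1L
    lvl <- if (motifs$methylated[i]) 0.9 else 0.05
    meth_vals[[ch]][pos] <- lvl
    meth_vals[[ch]][pos + 1L] <- lvl
  }
  methylation <- signal_track(meth_vals, counts = FALSE)

  ## --- genes, expression, eQTLs ------------------------------------------
  gpc <- round(cfg$n_genes * cfg$chrom_lengths / sum(cfg$chrom_lengths))
  gpc[1] <- cfg$n_genes - sum(gpc[-1])
  genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    data.frame(gene = character(gpc[ci]), chrom = chroms[ci],
               tss = .spaced_positions(gpc[ci], 2000L,
                                       cfg$chrom_lengths[ci] - 2000L, 5000L),
               stringsAsFactors = FALSE)
  }))
  genes$gene <- sprintf("G%03d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$expressed <- stats::runif(nrow(genes)) < cfg$expressed_frac
  genes$control <- stats::rlnorm(nrow(genes), cfg$expr_meanlog, cfg$expr_sdlog)
  domains <- build_domains(genes, chrom_lengths = cfg$chrom_lengths)
  rem <- motifs[motifs$remodeled, , drop = FALSE]
  has_rem <- vapply(seq_len(nrow(genes)), function(i) {
    d <- domains[domains$gene == genes$gene[i], , drop = FALSE]
    if (!nrow(d)) return(FALSE)
    any(rem$chrom == d$chrom & rem$center >= d$start & rem$center <= d$end)
  }, TRUE)
  fold <- ifelse(has_rem, cfg$expr_fold, 1)
  genes$induced <- genes$control * fold *
    stats::rlnorm(nrow(genes), 0, cfg$expr_noise_sdlog)
  genes$true_fold <- fold
  genes <- genes[, c("gene", "chrom", "strand", "tss", "expressed",
                     "control", "induced", "true_fold")]
  eq_gene <- sample(genes$gene, cfg$n_eqtl, replace = TRUE)
  eq_tss <- genes$tss[match(eq_gene, genes$gene)]
  eq_chrom <- genes$chrom[match(eq_gene, genes$gene)]
  eq_pos <- eq_tss + sample(c(-1, 1), cfg$n_eqtl, replace = TRUE) *
    sample(5000:150000, cfg$n_eqtl, replace = TRUE)
  eq_pos <- pmin(pmax(eq_pos, 1L), cfg$chrom_lengths[eq_chrom])
  eqtls <- data.frame(chrom = eq_chrom, pos = eq_pos, genes = eq_gene,
                      stringsAsFactors = FALSE)

  pairs_truth <- data.frame(
    pair_id = seq_along(pair_rows),
    chrom = locus$chrom[pair_rows],
    start_a = locus$start[pair_rows],
    start_b = locus$start[pair_rows] + pair_d,
    distance = pair_d,
    in_band = pair_d >= band[1] & pair_d <= band[2],
    stringsAsFactors = FALSE)

  structure(list(
    genome = genome,
    pwm = motif,
    partner_pwms = partners,
    tracks = list(atac_pre = atac_pre, atac_post = atac_post,
                  chip = chip, chip_control = chip_control,
                  mappability = mappability, conservation = conservation,
                  methylation = methylation),
    blacklist = blacklist,
    genes = genes,
    eqtls = eqtls,
    truth = list(motifs = motifs, pairs = pairs_truth,
                 partners = partner_truth, genes = genes),
    config = cfg), class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  m <- x$truth$motifs
  cat("synth_data:", sum(nchar(x$genome)), "bp on", length(x$genome),
      "chromosome(s)\n")
  cat("  planted motifs:", nrow(m), "(", sum(m$bound), "bound,",
      sum(m$cpg_core), "CpG-core,", nrow(x$truth$pairs), "pairs )\n")
  cat("  cut libraries: pre", x$tracks$atac_pre$library_size,
      "/ post", x$tracks$atac_post$library_size, "\n")
  invisible(x)
}

#' Write a synthetic experiment to standard file formats
#'
#' FASTA genome, BED blacklist, bedGraph tracks, PWM file and TSV tables,
#' the same formats a real-data run would consume.
#'
#' @param data A `synth_data` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synth_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    pwm = file.path(dir, "motifs.pwm"),
    blacklist = file.path(dir, "blacklist.bed"),
    genes = file.path(dir, "genes.tsv"),
    eqtls = file.path(dir, "eqtls.tsv"),
    truth_motifs = file.path(dir, "truth_motifs.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(data$genome), paths["genome"])
  write_pwm(c(list(data$pwm), data$partner_pwms), paths["pwm"])
  write_bed(data$blacklist, paths["blacklist"])
  write_gene_table(data$genes, paths["genes"])
  write_gene_table(data$eqtls, paths["eqtls"])
  write_gene_table(data$truth$motifs, paths["truth_motifs"])
  for (nm in names(data$tracks)) {
    p <- file.path(dir, paste0(nm, ".bedGraph"))
    write_bedgraph(data$tracks[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}
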