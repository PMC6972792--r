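#' Mappability and blacklist filtering of motif matches
#'
#' Each match is extended to a `width`-bp centered region; regions
#' overlapping the blacklist by at least one base are removed, then regions
#' with mean mappability below `min_mappability` are removed. The surviving
#' matches are returned with their original coordinates.
#'
#' @param matches `GRanges` of motif matches (from [scan_genome()]).
#' @param mappability A ratio `signal_track` of per-base mappability.
#' @param blacklist `GRanges` of blacklisted regions.
#' @param width Width of the centered evaluation window (default 200 bp).
#' @param min_mappability Minimum mean mappability kept (inclusive).
#' @return The retained subset of `matches`.
#' @export
mappability_filter <- function(matches, mappability, blacklist,
                               width = 200, min_mappability = 0.8) {
  if (length(matches) == 0L) return(matches)
  win <- GenomicRanges::resize(matches, width = width, fix = "center",
                               ignore.strand = TRUE)
  ok <- !IRanges::overlapsAny(win, blacklist, ignore.strand = TRUE)
  m <- interval_means(mappability, win)
  ok <- ok & !is.na(m) & m >= min_mappability
  matches[ok]
}

#' Flag motifs with no binding signal in any profiled sample
#'
#' A motif is a "no-signal" (unbound-universe) motif when, in every ChIP
#' track, the library-normalized tag count (tags per 10^7) in a `width`-bp
#' motif-centered window stays at or below `max_norm`. Motifs exceeding the
#' cutoff in any sample carry evidence of binding somewhere and are not
#' usable as unbound controls.
#'
#' @param matches `GRanges` of motif matches.
#' @param chip_tracks List of count `signal_track`s (one per sample).
#' @param width Window width (default 200 bp).
#' @param max_norm Maximum normalized count still called no-signal
#'   (boundary inclusive).
#' @return `matches` with a logical metadata column `no_signal`.
#' @export
no_signal_motifs <- function(matches, chip_tracks, width = 200, max_norm = 3) {
  stopifnot(length(chip_tracks) >= 1)
  win <- GenomicRanges::resize(matches, width = width, fix = "center",
                               ignore.strand = TRUE)
  flag <- rep(TRUE, length(matches))
  for (tr in chip_tracks) {
    if (is.null(tr$library_size)) stop("ChIP tracks must carry library sizes")
    norm <- normalize_counts(interval_sums(tr, win), tr$library_size)
    flag <- flag & norm <= max_norm
  }
  S4Vectors::mcols(matches)$no_signal <- flag
  matches
}

# start-to-start distance to the nearest other match on the same chromosome
.nearest_start_distance <- function(matches) {
  out <- rep(Inf, length(matches))
  chroms <- as.character(GenomicRanges::seqnames(matches))
  st <- GenomicRanges::start(matches)
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    if (length(i) < 2) next
    o <- order(st[i])
    s <- st[i][o]
    gaps <- diff(s)
    d <- pmin(c(Inf, gaps), c(gaps, Inf))
    out[i][o] <- d
  }
  out
}

#' Flag motifs carrying a core-proximal CpG
#'
#' Marks matches whose strand-oriented sequence shows a CpG immediately 5'
#' of the invariant GGAA core (pattern CGGAA starting one base before the
#' core). For the methylation analysis, matches with another match of the
#' same motif within `pair_radius` bases (start-to-start) are excluded,
#' since binding signal there may derive from the unmethylated neighbor.
#'
#' @param matches `GRanges` with a `word` metadata column (strand-oriented
#'   sequence, as emitted by [scan_genome()]).
#' @param genome Optional genome (named character vector) used to extract
#'   words when the `word` column is absent.
#' @param core_offset 1-based offset of the GGAA core within the motif;
#'   must be >= 2 so the CpG position exists.
#' @param pair_radius Neighbor-exclusion radius in bases (default 150).
#' @return `matches` with logical metadata columns `cpg_core` and
#'   `meth_eligible` (CpG-core matches without a near neighbor).
#' @export
classify_cpg_core <- function(matches, genome = NULL, core_offset,
                              pair_radius = 150) {
  if (missing(core_offset) || is.null(core_offset) || core_offset < 2)
    stop("`core_offset` must locate the GGAA core at column >= 2 of the PWM")
  words <- S4Vectors::mcols(matches)$word
  if (is.null(words)) {
    if (is.null(genome)) stop("matches lack a `word` column and no genome given")
    words <- .extract_words(matches, genome)
  }
  cpg <- substr(words, core_offset - 1L, core_offset + 3L) == "CGGAA"
  near <- .nearest_start_distance(matches) <= pair_radius
  S4Vectors::mcols(matches)$cpg_core <- cpg
  S4Vectors::mcols(matches)$meth_eligible <- cpg & !near
  matches
}

# strand-oriented sequences under a set of matches
.extract_words <- function(matches, genome) {
  chroms <- as.character(GenomicRanges::seqnames(matches))
  words <- substring(genome[chroms], GenomicRanges::start(matches),
                     GenomicRanges::end(matches))
  minus <- as.character(GenomicRanges::strand(matches)) == "-"
  if (any(minus))
    words[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(words[minus])))
  toupper(words)
}

#' Word-matched random control motifs
#'
#' Draws, for every distinct nucleotide word among the target matches, the
#' same number of no-signal pool matches carrying that exact word (as many
#' as the pool holds), uniformly without replacement. Matching on the word
#' removes the score bias a naive random draw would carry, since the word
#' determines the motif score.
#'
#' @param targets `GRanges` of target matches with a `word` column.
#' @param pool `GRanges` of candidate control matches (disjoint from
#'   `targets`) with a `word` column.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A list with `controls` (subset of `pool`) and `shortfall`
#'   (named integer vector: target words minus controls obtained; only
#'   words with a positive shortfall are listed).
#' @export
matched_control_sample <- function(targets, pool, seed = 1L) {
  tw <- S4Vectors::mcols(targets)$word
  pw <- S4Vectors::mcols(pool)$word
  if (is.null(tw) || is.null(pw)) stop("both inputs need a `word` column")
  need <- table(tw)
  picked <- integer(0)
  short <- integer(0)
  with_local_seed(seed, {
    for (w in names(need)) {
      avail <- which(pw == w)
      k <- min(need[[w]], length(avail))
      if (k > 0) picked <- c(picked, avail[sample.int(length(avail), k)])
      if (k < need[[w]]) short[w] <- need[[w]] - k
    }
  })
  list(controls = pool[sort(picked)], shortfall = short)
}

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
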