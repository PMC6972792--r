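#' Position weight matrices
#'
#' A `pwm` bundles a base-probability matrix with its background
#' frequencies, a log-odds score threshold and (optionally) the offset of
#' the biologically fixed core within the consensus (1-based column of the
#' first core base). Scores are natural-log odds: `sum(ln(p_i(base) /
#' bg(base)))` with a pseudocount of 1e-3 added to every probability (and
#' the row renormalized) so no column is degenerate.
#'
#' @param probs Numeric matrix, width x 4, columns A, C, G, T; each row sums
#'   to 1 (within 1e-9).
#' @param name Motif name.
#' @param background Length-4 background base frequencies (A, C, G, T).
#' @param threshold Log-odds cutoff used by [scan_genome()].
#' @param core_offset Optional 1-based column where the invariant core
#'   (e.g. GGAA) starts.
#' @return An object of class `pwm`.
#' @export
pwm <- function(probs, name = "motif", background = rep(0.25, 4),
                threshold = 0, core_offset = NULL) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4, nrow(probs) >= 2)
  if (any(abs(rowSums(probs) - 1) > 1e-9)) stop("PWM rows must sum to 1")
  if (any(probs < 0)) stop("PWM probabilities must be non-negative")
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(name = name, probs = probs, background = background,
                 threshold = threshold, core_offset = core_offset),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$name, ": width", nrow(x$probs),
      ", threshold", format(x$threshold))
  if (!is.null(x$core_offset)) cat(", core offset", x$core_offset)
  cat("\n  consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Width of a PWM
#' @param x A `pwm`.
#' @export
pwm_width <- function(x) nrow(x$probs)

#' Consensus sequence (per-column argmax) of a PWM
#' @param x A `pwm`.
#' @export
pwm_consensus <- function(x) {
  paste(colnames(x$probs)[max.col(x$probs, ties.method = "first")],
        collapse = "")
}

# width x 5 natural-log odds matrix (A,C,G,T,N); pseudocount 1e-3,
# N scores as the column minimum so N windows effectively fail thresholds.
pwm_logodds <- function(x, pseudocount = 1e-3) {
  p <- (x$probs + pseudocount) / (1 + 4 * pseudocount)
  lo <- log(sweep(p, 2, x$background, "/"))
  cbind(lo, N = apply(lo, 1, min))
}

#' Reverse complement of a PWM
#'
#' Rows are reversed and complementary base columns swapped; the background
#' is complement-swapped likewise.
#'
#' @param x A `pwm`.
#' @return A `pwm` scoring the opposite strand.
#' @export
pwm_reverse_complement <- function(x) {
  p <- x$probs[rev(seq_len(nrow(x$probs))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(p) <- c("A", "C", "G", "T")
  co <- NULL
  pwm(p, name = x$name, background = x$background[c(4, 3, 2, 1)],
      threshold = x$threshold, core_offset = co)
}

#' Score one sequence window under a PWM
#'
#' @param x A `pwm`.
#' @param seq Character scalar over A/C/G/T/N with `nchar(seq) ==
#'   pwm_width(x)`.
#' @return Natural-log odds score; each N contributes that column's
#'   minimum log-odds.
#' @export
score_sequence <- function(x, seq) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  w <- pwm_width(x)
  if (nchar(seq) != w)
    stop("sequence length ", nchar(seq), " != PWM width ", w)
  codes <- .encode_bases(seq)
  lo <- pwm_logodds(x)
  sum(lo[cbind(seq_len(w), codes)])
}

# map a nucleotide string to integer codes 1..5 (A,C,G,T,N/other)
.encode_bases <- function(seq) {
  lut <- rep(5L, 256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(seq)]
}

#' Scan a genome for motif matches on both strands
#'
#' Reports every offset, on either strand, whose log-odds score reaches the
#' threshold. Minus-strand windows are scored on their reverse complement
#' and reported in reference coordinates; overlapping opposite-strand
#' matches at one locus are both kept.
#'
#' @param x A `pwm`.
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param threshold Log-odds cutoff; defaults to `x$threshold`.
#' @return A `GRanges` of matches with metadata columns `score` (log-odds),
#'   `word` (the strand-oriented sequence under the match) and `motif`.
#' @export
scan_genome <- function(x, genome, threshold = x$threshold) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome), !is.null(names(genome)))
  w <- pwm_width(x)
  lo <- pwm_logodds(x)
  # minus-strand log-odds in reference orientation:
  # rc_lo[k, b] = lo[w + 1 - k, complement(b)]
  rc_lo <- lo[rev(seq_len(w)), c(4L, 3L, 2L, 1L, 5L), drop = FALSE]
  seqlens <- stats::setNames(nchar(genome), names(genome))
  hits <- list()
  for (ch in names(genome)) {
    n <- nchar(genome[[ch]])
    if (n < w) next
    codes <- .encode_bases(genome[[ch]])
    m <- n - w + 1L
    fwd <- numeric(m)
    rev_ <- numeric(m)
    for (j in seq_len(w)) {
      cj <- codes[j:(m + j - 1L)]
      fwd <- fwd + unname(lo[j, ])[cj]
      rev_ <- rev_ + unname(rc_lo[j, ])[cj]
    }
    for (str in c("+", "-")) {
      sc <- if (str == "+") fwd else rev_
      at <- which(sc >= threshold)
      if (!length(at)) next
      words <- substring(genome[[ch]], at, at + w - 1L)
      if (str == "-")
        words <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(words)))
      hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
        factor(ch, levels = names(genome)),
        IRanges::IRanges(at, width = w), strand = str,
        score = sc[at], word = toupper(words), motif = x$name)
    }
  }
  if (!length(hits)) {
    out <- GenomicRanges::GRanges(score = numeric(), word = character(),
                                  motif = character())
  } else {
    out <- sort(do.call(c, hits), ignore.strand = TRUE)
  }
  GenomeInfoDb::seqlevels(out) <- names(genome)
  GenomeInfoDb::seqlengths(out) <- seqlens
  out
}

#' Read / write PWM files
#'
#' Plain-text format: one header line `>name core_offset=K threshold=T`
#' followed by width rows of four tab-separated probabilities (A, C, G, T);
#' multiple records per file are allowed.
#'
#' @param file Path to a PWM file.
#' @param background Background frequencies attached to every record.
#' @return `read_pwm` returns a named list of `pwm` objects.
#' @export
read_pwm <- function(file, background = rep(0.25, 4)) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no PWM records (lines starting with '>') in ", file)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>", "", lines[starts[i]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    name <- toks[1]
    kv <- toks[-1]
    getnum <- function(key) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(hit)) as.numeric(sub(".*=", "", hit[1])) else NULL
    }
    rows <- lines[(starts[i] + 1L):ends[i]]
    probs <- do.call(rbind, lapply(strsplit(rows, "\t| +"), as.numeric))
    out[[name]] <- pwm(probs, name = name, background = background,
                       threshold = getnum("threshold") %||% 0,
                       core_offset = getnum("core_offset"))
  }
  out
}

#' @rdname read_pwm
#' @param x A `pwm` or list of `pwm` objects to write.
#' @export
write_pwm <- function(x, file) {
  if (inherits(x, "pwm")) x <- list(x)
  con <- file(file, "w")
  on.exit(close(con))
  for (p in x) {
    hdr <- paste0(">", p$name)
    if (!is.null(p$core_offset)) hdr <- paste0(hdr, " core_offset=", p$core_offset)
    hdr <- paste0(hdr, " threshold=", format(p$threshold, digits = 12))
    writeLines(hdr, con)
    utils::write.table(format(p$probs, digits = 8), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
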