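#' Build gene regulatory domains
#'
#' Every expressed gene receives a basal domain of `basal` bases up- and
#' downstream of its TSS regardless of neighbors. The domain is then
#' extended in each direction to the nearest neighboring gene's basal
#' boundary, but never further than `cap` bases from the TSS and never
#' retracting inside the gene's own basal domain.
#'
#' @param genes Data frame with columns `gene`, `chrom`, `strand`, `tss`
#'   (1-based position) and logical `expressed`; only expressed genes enter
#'   domain construction.
#' @param basal Basal half-width in bases (default 25000).
#' @param cap Maximum extension from the TSS in one direction
#'   (default 250000).
#' @param chrom_lengths Optional named vector used to clip domain ends.
#' @return A data frame: `gene`, `chrom`, `tss`, `basal_start`,
#'   `basal_end`, `start`, `end` (1-based closed, clipped at chromosome
#'   bounds).
#' @export
build_domains <- function(genes, basal = 25000, cap = 250000,
                          chrom_lengths = NULL) {
  g <- genes[genes$expressed, , drop = FALSE]
  if (!nrow(g))
    return(data.frame(gene = character(), chrom = character(), tss = integer(),
                      basal_start = numeric(), basal_end = numeric(),
                      start = numeric(), end = numeric()))
  g <- g[order(g$chrom, g$tss), , drop = FALSE]
  out <- lapply(split(g, g$chrom), function(gc) {
    tss <- gc$tss
    n <- nrow(gc)
    bs <- tss - basal
    be <- tss + basal
    # nearest neighbor basal boundaries per direction
    left_nb <- c(NA, tss[-n] + basal)    # right basal edge of left neighbor
    right_nb <- c(tss[-1] - basal, NA)   # left basal edge of right neighbor
    ext_l <- pmax(tss - cap, ifelse(is.na(left_nb), tss - cap, left_nb))
    ext_r <- pmin(tss + cap, ifelse(is.na(right_nb), tss + cap, right_nb))
    # never retract inside the basal domain
    start <- pmin(bs, ext_l)
    end <- pmax(be, ext_r)
    data.frame(gene = gc$gene, chrom = gc$chrom, tss = tss,
               basal_start = bs, basal_end = be, start = start, end = end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$basal_start <- pmax(out$basal_start, 1)
  out$start <- pmax(out$start, 1)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[out$chrom]
    out$basal_end <- pmin(out$basal_end, len)
    out$end <- pmin(out$end, len)
  }
  out
}

# minimum gap between a region [s, e] and a point p (0 if inside)
.region_point_distance <- function(s, e, p) {
  pmax(0, pmax(s - p, p - e))
}

#' Assign a genomic region to genes
#'
#' Stepwise priority: (1) *TSS* — all expressed genes whose TSS lies
#' within `tss_dist` bases of the region boundary; (2) *eQTL* — if promoter
#' distal, the union of genes linked to any eQTL SNP within `eqtl_dist`
#' bases; (3) *domain* — all genes whose extended regulatory domain
#' overlaps the region; otherwise `none`. Distances are measured from the
#' region boundary (0 inside the region).
#'
#' @param region A length-1 `GRanges` (or list with `chrom`, `start`,
#'   `end`, 1-based closed).
#' @param genes Gene data frame (see [build_domains()]).
#' @param domains Output of [build_domains()] for the same genes.
#' @param eqtls Data frame with `chrom`, `pos` (1-based SNP position) and
#'   `genes` (comma-separated gene ids), or NULL.
#' @param tss_dist,eqtl_dist Maximum distances in bases (default 1000).
#' @return A list with `genes` (character vector, possibly empty) and
#'   `mode` (`"TSS"`, `"eQTL"`, `"domain"` or `"none"`).
#' @export
assign_region <- function(region, genes, domains, eqtls = NULL,
                          tss_dist = 1000, eqtl_dist = 1000) {
  if (methods::is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    ch <- as.character(GenomicRanges::seqnames(region))
    s <- GenomicRanges::start(region)
    e <- GenomicRanges::end(region)
  } else {
    ch <- region$chrom; s <- region$start; e <- region$end
  }
  expressed <- genes[genes$expressed, , drop = FALSE]
  gi <- which(expressed$chrom == ch &
                .region_point_distance(s, e, expressed$tss) <= tss_dist)
  if (length(gi)) return(list(genes = unique(expressed$gene[gi]), mode = "TSS"))
  if (!is.null(eqtls) && nrow(eqtls)) {
    si <- which(eqtls$chrom == ch &
                  .region_point_distance(s, e, eqtls$pos) <= eqtl_dist)
    if (length(si)) {
      gs <- unique(unlist(strsplit(eqtls$genes[si], ",")))
      gs <- trimws(gs)
      gs <- gs[gs %in% genes$gene]
      if (length(gs)) return(list(genes = gs, mode = "eQTL"))
    }
  }
  di <- which(domains$chrom == ch & domains$start <= e & domains$end >= s)
  if (length(di)) return(list(genes = unique(domains$gene[di]), mode = "domain"))
  list(genes = character(), mode = "none")
}

#' Assign many regions at once
#'
#' @param regions `GRanges` of regions.
#' @inheritParams assign_region
#' @return A data frame with one row per (region, gene) link plus unassigned
#'   regions (`gene = NA`): `region_index`, `gene`, `mode`.
#' @export
assign_regions <- function(regions, genes, domains, eqtls = NULL,
                           tss_dist = 1000, eqtl_dist = 1000) {
  rows <- lapply(seq_along(regions), function(i) {
    a <- assign_region(regions[i], genes, domains, eqtls,
                       tss_dist = tss_dist, eqtl_dist = eqtl_dist)
    if (!length(a$genes))
      return(data.frame(region_index = i, gene = NA_character_, mode = a$mode,
                        stringsAsFactors = FALSE))
    data.frame(region_index = i, gene = a$genes, mode = a$mode,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-cluster paired expression test
#'
#' For each peak cluster, tests whether the expression of the cluster's
#' uniquely assigned genes is higher after induction, with a one-sided
#' paired Wilcoxon signed-rank test (exact null for n <= 25 without ties,
#' normal approximation with tie/continuity correction otherwise).
#' Clusters with fewer than 3 assigned genes are reported untested (NA).
#'
#' @param assignments Data frame with columns `gene` and `cluster` (one row
#'   per peak-gene link; genes are deduplicated within a cluster).
#' @param expression Data frame with columns `gene`, `control`, `induced`
#'   (identically normalized units).
#' @return A data frame per cluster: `cluster`, `n_genes`, `pvalue`,
#'   `direction` (`"up"` when the median paired difference is positive),
#'   `stars`.
#' @export
cluster_expression_test <- function(assignments, expression) {
  ex <- expression[!duplicated(expression$gene), , drop = FALSE]
  rownames(ex) <- ex$gene
  res <- lapply(sort(unique(assignments$cluster)), function(cl) {
    gs <- unique(assignments$gene[assignments$cluster == cl])
    gs <- gs[!is.na(gs) & gs %in% ex$gene]
    n <- length(gs)
    if (n < 3)
      return(data.frame(cluster = cl, n_genes = n, pvalue = NA_real_,
                        direction = NA_character_, stars = "",
                        stringsAsFactors = FALSE))
    ind <- ex[gs, "induced"]; ctl <- ex[gs, "control"]
    d <- ind - ctl
    exact <- n <= 25 && !any(d == 0) && !any(duplicated(abs(d[d != 0])))
    p <- suppressWarnings(stats::wilcox.test(
      ind, ctl, paired = TRUE, alternative = "greater",
      exact = exact, correct = TRUE)$p.value)
    if (all(d == 0)) p <- 1
    stars <- if (is.na(p)) "" else if (p <= 0.001) "***" else if (p <= 0.01)
      "**" else if (p <= 0.05) "*" else ""
    data.frame(cluster = cl, n_genes = n, pvalue = p,
               direction = if (stats::median(d) > 0) "up" else "down_or_flat",
               stars = stars, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read / write gene model and eQTL tables
#'
#' Gene models are 6+ column TSV: `gene`, `chrom`, `strand`, `tss`,
#' `expressed` (0/1), then one expression column per condition. eQTL
#' tables are 3-column TSV: `chrom`, `pos`, comma-separated `genes`.
#'
#' @param file Path to a tab-separated file with header.
#' @return A data frame.
#' @export
read_gene_table <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname read_gene_table
#' @param x Data frame to write.
#' @export
write_gene_table <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
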