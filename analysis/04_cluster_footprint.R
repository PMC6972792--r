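#!/usr/bin/env Rscript
# Stage 4 -- accessibility clustering and footprints.
#
# Clusters stringent-peak accessibility (300-bp windows, pre vs post
# induction, K = 14 on log2 counts) ordered by increasing pre-induction
# accessibility, reports the per-cluster remodeling index, and computes
# the single-base footprint profile over bound motifs.

source(file.path("analysis", "00_common.R"))

peaks_str <- call_peaks_factor(DATA$tracks$chip, DATA$tracks$chip_control,
                               stringent = TRUE)
cmat <- peak_count_matrix(peaks_str, DATA$tracks$atac_pre, DATA$tracks$atac_post)
clusters <- cluster_peaks(cmat, K = 14, seed = SEED)
print(clusters)
write_tsv(clusters$summary, "04_cluster_summary.tsv")

assign_out <- peaks_str
S4Vectors::mcols(assign_out)$name <- "."
S4Vectors::mcols(assign_out)$score <- 0
S4Vectors::mcols(assign_out)$cluster <- clusters$assignment
write_bed_plus(assign_out, file.path(RESULTS, "04_peak_clusters.bed"),
               extra_cols = "cluster")
message("  wrote ", file.path(RESULTS, "04_peak_clusters.bed"))

matches <- mappability_filter(scan_genome(DATA$pwm, DATA$genome),
                              DATA$tracks$mappability, DATA$blacklist)
bound <- intersect_intervals(matches, peaks_str, "a_with_any_overlap")
fp <- footprint_profile(bound, DATA$tracks$atac_post)
write_tsv(fp, "04_footprint_post.tsv")
center <- mean(fp$value[abs(fp$offset) <= 6])
flank <- mean(fp$value[abs(fp$offset) >= 50])
message(sprintf("footprint: central depletion %.2f of flank level (%d motifs)",
                center / flank, attr(fp, "n_motifs")))

n_high <- sum(clusters$summary$rem_index > 1)
message(sprintf("%d of %d clusters show Rem-Index > 1 (de novo remodeling)",
                n_high, clusters$K))
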