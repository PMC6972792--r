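#!/usr/bin/env Rscript
# Stage 3 -- peak and region calling.
#
# ChIP peaks in factor mode (standard and stringent: BH fdr <= 1e-5 and
# >= 15 normalized tags), ATAC regions in region mode (150-bp windows
# stitched below 250 bp, 2-fold gate), focal-region refinement
# (extend 48 / merge / reduce 24), and differential ATAC regions whose
# "down" class is the lost-accessibility site set.

source(file.path("analysis", "00_common.R"))

peaks_std <- call_peaks_factor(DATA$tracks$chip, DATA$tracks$chip_control)
peaks_str <- call_peaks_factor(DATA$tracks$chip, DATA$tracks$chip_control,
                               stringent = TRUE)
atac_pre <- call_peaks_region(DATA$tracks$atac_pre)
atac_post <- call_peaks_region(DATA$tracks$atac_post)
atac_all <- merge_intervals(c(atac_pre, atac_post), 0)
diff_atac <- differential_regions(list(DATA$tracks$atac_pre),
                                  list(DATA$tracks$atac_post), atac_all)

summary_tab <- data.frame(
  set = c("chip_standard", "chip_stringent", "atac_regions_pre",
          "atac_regions_post", "atac_lost", "atac_gained"),
  n = c(length(peaks_std), length(peaks_str), length(atac_pre),
        length(atac_post), length(diff_atac$down), length(diff_atac$up)),
  frip = c(frip(DATA$tracks$chip, peaks_std), NA,
           frip(DATA$tracks$atac_pre, atac_pre),
           frip(DATA$tracks$atac_post, atac_post), NA, NA))
print(summary_tab, digits = 3)
write_tsv(summary_tab, "03_peak_summary.tsv")

write_bed_plus(peaks_str, file.path(RESULTS, "03_chip_stringent.bed"),
               extra_cols = c("norm_count", "padj"))
message("  wrote ", file.path(RESULTS, "03_chip_stringent.bed"))

bound <- DATA$truth$motifs[DATA$truth$motifs$bound, ]
bgr <- GRanges(bound$chrom, IRanges::IRanges(bound$start, bound$end))
message(sprintf("bound truth sites covered by stringent peaks: %.1f%%",
                100 * mean(IRanges::overlapsAny(bgr, peaks_str))))
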