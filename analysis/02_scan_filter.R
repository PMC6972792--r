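#!/usr/bin/env Rscript
# Stage 2 -- genome-wide motif scan and motif-level filtering.
#
# Scans both strands for the factor motif and the partner-class motifs,
# then applies the mappability/blacklist filter (200-bp windows, mean
# mappability >= 0.8) and flags the no-signal (unbound-universe) motifs.
# The attrition table mirrors the funnel a real-data run reports.

source(file.path("analysis", "00_common.R"))

matches <- scan_genome(DATA$pwm, DATA$genome)
filtered <- mappability_filter(matches, DATA$tracks$mappability, DATA$blacklist)
filtered <- no_signal_motifs(filtered, list(DATA$tracks$chip))

attrition <- data.frame(
  stage = c("genome_bp", "motif_matches", "mappability_blacklist_filtered",
            "no_signal_unbound_universe"),
  n = c(sum(nchar(DATA$genome)), length(matches), length(filtered),
        sum(filtered$no_signal)))
print(attrition)
write_tsv(attrition, "02_motif_attrition.tsv")

# motif matches as BED6+ (score column = log-odds x 100, rounded)
out <- filtered
S4Vectors::mcols(out)$name <- out$motif
S4Vectors::mcols(out)$score <- round(out$score * 100)
write_bed_plus(out, file.path(RESULTS, "02_motifs_filtered.bed"),
               extra_cols = c("word", "no_signal"))
message("  wrote ", file.path(RESULTS, "02_motifs_filtered.bed"))

truth_idx <- match_truth(filtered, DATA$truth$motifs)
message(sprintf("planted motifs recovered after filtering: %d / %d",
                length(unique(stats::na.omit(truth_idx))),
                nrow(DATA$truth$motifs)))
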