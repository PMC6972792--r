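#!/usr/bin/env Rscript
# Stage 6 -- regulatory domains, peak-to-gene assignment and per-cluster
# expression tests.
#
# Builds basal (+/-25 kb) and extended (<= 250 kb) regulatory domains for
# expressed genes, assigns each stringent peak by the TSS > eQTL > domain
# priority, and tests each accessibility cluster's genes for induction
# with a one-sided paired Wilcoxon test.

source(file.path("analysis", "00_common.R"))

peaks_str <- call_peaks_factor(DATA$tracks$chip, DATA$tracks$chip_control,
                               stringent = TRUE)
cmat <- peak_count_matrix(peaks_str, DATA$tracks$atac_pre, DATA$tracks$atac_post)
clusters <- cluster_peaks(cmat, K = 14, seed = SEED)

domains <- build_domains(DATA$genes, chrom_lengths = DATA$config$chrom_lengths)
write_tsv(domains, "06_domains.tsv")
assignment <- assign_regions(peaks_str, DATA$genes, domains, DATA$eqtls)
assignment$cluster <- clusters$assignment[assignment$region_index]
write_tsv(assignment, "06_assignment.tsv")
message("assignment modes:")
print(table(assignment$mode[!duplicated(assignment$region_index)]))

et <- cluster_expression_test(assignment[!is.na(assignment$gene), ],
                              DATA$genes[, c("gene", "control", "induced")])
et$rem_index <- clusters$summary$rem_index[et$cluster]
write_tsv(et, "06_cluster_expression.tsv")
print(et, digits = 3)
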