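#!/usr/bin/env Rscript
# Stage 1 -- simulate the two-condition experiment.
#
# Generates the benchmark synthetic dataset: a 2-Mb genome with 2,000
# planted factor motifs (singletons and homotypic pairs), pre/post-
# induction Tn5 cut tracks, ChIP tag tracks, annotation tracks, genes and
# eQTLs, and exports the ground-truth tables the later stages are
# evaluated against.

source(file.path("analysis", "00_common.R"))

print(DATA)
m <- DATA$truth$motifs
message(sprintf("classes: %s", paste(names(table(m$class)),
                                     table(m$class), collapse = ", ")))
message(sprintf("bound in truth: %d (%.1f%%); CpG-core: %d; methylated: %d",
                sum(m$bound), 100 * mean(m$bound), sum(m$cpg_core),
                sum(m$methylated)))

write_tsv(m, "01_truth_motifs.tsv")
write_tsv(DATA$truth$pairs, "01_truth_pairs.tsv")
write_tsv(DATA$genes, "01_genes.tsv")
write_tsv(DATA$eqtls, "01_eqtls.tsv")
write_pwm(c(list(DATA$pwm), DATA$partner_pwms),
          file.path(RESULTS, "01_motifs.pwm"))
message("  wrote ", file.path(RESULTS, "01_motifs.pwm"))
# full track/FASTA export is bulky; regenerate with write_synth_data()
# under scratch/ when files are needed by external tools
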