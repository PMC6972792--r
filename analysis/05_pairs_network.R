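#!/usr/bin/env Rscript
# Stage 5 -- homotypic pairs and the motif-class co-occurrence network.
#
# Enumerates homotypic motif pairs (<= 150 bp, start-to-start), splits
# them into bound/unbound by stringent-peak overlap, tests every spacing
# for hypergeometric enrichment in the bound fraction, and builds the
# per-peak motif-class network (node/edge fractions of peaks).

source(file.path("analysis", "00_common.R"))

matches <- mappability_filter(scan_genome(DATA$pwm, DATA$genome),
                              DATA$tracks$mappability, DATA$blacklist)
peaks_str <- call_peaks_factor(DATA$tracks$chip, DATA$tracks$chip_control,
                               stringent = TRUE)

pairs <- classify_pairs_bound(enumerate_pairs(matches), matches, peaks_str)
write_tsv(pairs[, c("chrom", "start_a", "start_b", "distance", "orientation",
                    "score_a", "score_b", "bound")], "05_pairs.tsv")
en <- distance_enrichment(pairs)
write_tsv(en$table, "05_distance_enrichment.tsv")
sig <- en$table$distance[en$table$significant]
message(sprintf("%d pairs (%d bound); significant spacings: %s",
                en$n_pairs, en$n_bound,
                paste(range(sig), collapse = "-")))
print(en$band_summary, digits = 3)

singles <- single_motifs(matches)
message(sprintf("single motifs (no neighbor within 150 bp): %d",
                length(singles)))

partner_matches <- lapply(DATA$partner_pwms, scan_genome,
                          genome = DATA$genome)
pcm <- peak_class_matrix(peaks_str, matches, partner_matches)
net <- build_network(pcm)
write_tsv(net$nodes, "05_network_nodes.tsv")
write_tsv(net$edges, "05_network_edges.tsv")
print(net$nodes, digits = 3)
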