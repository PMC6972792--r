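# Shared setup for the numbered analysis scripts: parse the seed, create
# the results directory, and provide the benchmark experiment (generated
# once per script run; generation is deterministic in the seed).

suppressPackageStartupMessages({
  library(pioneerscan)
  library(GenomicRanges)
})

args <- commandArgs(trailingOnly = TRUE)
SEED <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

message("benchmark experiment, seed ", SEED)
DATA <- generate(benchmark_config(seed = SEED))

write_tsv <- function(x, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
  path
}
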