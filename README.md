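# pioneerscan

Tools for dissecting how an ectopically induced transcription factor
selects its genomic binding sites from the vast excess of equally good
sequence motifs. When a hematopoietic ETS factor such as PU.1 is switched
on in a cell type that never expressed it, only a small fraction of its
~10^6 genomic recognition sequences becomes bound, some in already-open
chromatin and some at sites the factor's recruited remodeling machinery
opens de novo. This package implements the complete computational
workflow of that dissection — for computational biologists who want to
run, extend or stress-test the analysis on fully controlled synthetic
data with exported ground truth.

## What it computes

* **Motif universe** — genome-wide PWM scanning on both strands with
  natural-log odds scores `s(x) = Σ_i ln(p_i(x_i) / q(x_i))`, followed by
  the motif-level filters: 200-bp mappability windows (mean ≥ 0.8),
  blacklist subtraction, and the *no-signal* universe (≤ 3 tags per 10^7
  in a 200-bp window in every ChIP sample) that serves as the unbound
  control world, with word-matched random control draws.
* **Peaks** — a documented Poisson/Benjamini–Hochberg stand-in caller
  with *factor* mode (fixed 200-bp windows, greedy local maxima) and
  *region* mode (150-bp windows stitched below 250 bp with a 2-fold
  gate), a stringent class (BH fdr ≤ 1e-5 **and** ≥ 15 normalized tags),
  differential regions by a two-sided Poisson rate test, and FRIP QC.
* **Accessibility** — Tn5 +4/−5 cut-site shifting, peak-centered 300-bp
  count matrices pre/post induction, K-means clustering (K = 14 on
  log2 counts, ordered by pre-induction accessibility) with a per-peak
  remodeling index `log2((post + 1)/(pre + 1))`, and single-base
  footprint profiles.
* **Motif grammar** — homotypic pair enumeration (≤ 150 bp), exact
  hypergeometric spacing enrichment in the bound fraction (`phyper`),
  single-motif definition, PWM-correlation reduction of motifs to known
  classes (r > 0.85), and per-peak co-occurrence networks.
* **Genes** — GREAT-style regulatory domains (basal ± 25 kb, extension
  to the neighbor's basal domain capped at 250 kb), stepwise
  TSS → eQTL → domain assignment, and one-sided paired Wilcoxon tests of
  cluster-wise expression induction.
* **Prediction** — logistic models of bound vs unbound motifs over
  nested predictor sets (sequence; + pre-ATAC; + post-ATAC), ridge-
  stabilized IRLS, seeded random half splits, and ROC/AUC comparison.
* **Synthetic data** — a fully seeded generator emulating the
  two-condition experiment: planted motifs with class structure
  (de-novo-remodeled / pre-accessible / unbound / lost), spacing-
  cooperative homotypic pairs, partner-motif co-planting, CpG-core
  methylation that suppresses binding, footprint-shaped cut depletion,
  and expression fold changes coupled to remodeled regulatory domains.

## Worked example

```r
library(pioneerscan)

data <- generate(benchmark_config(seed = 1))   # 2 Mb, 2,000 planted motifs
run  <- run_pipeline(data, pred_seed = 1)
run$prediction
#>                 set       auc seed
#> 1          sequence 0.7974981    1
#> 2      sequence_pre 0.8199023    1
#> 3 sequence_pre_post 0.8703489    1
```

The AUC ordering is the study's central observation in miniature:
knowing the sequence (score, conservation, co-motifs) predicts binding
imperfectly; adding pre-induction accessibility helps; accessibility
*after* induction is the best predictor, because a large share of
binding happens at sites the factor itself opens. Other numbers the same
run prints: 3,321 motif matches of which 3,253 survive filtering; 528
stringent peaks covering 98.5% of truly bound sites; a footprint whose
central cut density is 0.51 of the flank level; pair spacings 15–45 bp
flagged enriched in the bound fraction at 87% coverage with no false
flags elsewhere.

The same workflow, stage by stage with result tables written under
`results/`, is in the numbered scripts:

```sh
Rscript analysis/01_simulate.R 1      # ... through analysis/07_predict.R
```

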