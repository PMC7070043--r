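# dexhet

Cell-to-cell heterogeneity in the glucocorticoid transcriptional response,
quantified from single-cell RNA-seq.

Glucocorticoids act through the glucocorticoid receptor (GR), and bulk
RNA-seq of a dexamethasone (Dex) time course shows hundreds of genes
responding. Single-cell data reveal what the average hides: an individual
hormone-treated cell responds at only a fraction of the population's
target genes. `dexhet` implements the full analysis chain used to measure
that heterogeneity, plus a synthetic-data generator that emulates the
study design (six conditions — vehicle "0h" and 1, 2, 4, 8, 18 h of Dex —
with 400 cells per condition after QC), so every stage is testable against
known ground truth with no downloads.

## What it computes

For each responsive gene $g$, the vehicle (EtOH) baseline mean $m_g$ and
sample SD $s_g$ of log-normalized expression are computed over *expressing*
vehicle cells (zeros excluded, so dropout cannot deflate the baseline). A
cell "responds" at an induced gene when its expression exceeds
$m_g + s_g$ (strictly), or falls below $m_g - s_g$ for a repressed gene.
Two marginals of the resulting indicator matrix summarize heterogeneity:

* **RRG** (Ratio of Responding Genes) — per cell, the fraction of the
  differentially-expressed-gene (DEG) superset at which it responds;
* **RC%** (Responding-Cell percentage) — per gene and timepoint, the
  fraction of cells responding.

Their timepoint means coincide exactly (both average the same indicator
matrix). Upstream of these sit a tagged-read demultiplexer (Hamming-1
barcode correction, density-valley cell calling, per-gene UMI
deduplication), QC/normalization/covariate regression, and a two-part
(hurdle) differential-expression test with the cutoffs
|fold change| ≥ 1.25, BH-adjusted p < 0.01, ≥ 10% detection. Downstream, a
gene–gene Pearson correlation analysis is calibrated against 1,000 random
gene sets matched to the DEG expression-decile profile, asking whether
response co-ordination exceeds what similarly expressed genes show.

## Worked example

```r
library(dexhet)

cfg <- sim_config(n_genes = 800, cells_per_timepoint = 200, seed = 5)
res <- run_dex_pipeline(cfg)   # simulate -> QC -> normalize -> DE -> RRG/RC%
print(res$sim)
#> Simulated count matrix: 800 genes x 1200 cells (0h, 1h, 2h, 4h, 8h, 18h)
#>   median transcripts/cell: 22806; median genes/cell: 339

head(res$superset[order(-res$superset$max_abs_log2fc), ], 5)
#>     gene direction n_timepoints timepoints max_abs_log2fc
#> 5 g00613         1            2     8h,18h       2.227236
#> 3 g00432         1            2     8h,18h       2.138040
#> 4 g00488         1            2     8h,18h       2.123141
#> 2 g00425         1            2     8h,18h       1.707117
#> 8 g00768         1            1        18h       1.400604

rrg_mean <- tapply(res$rrg_table$rrg, res$rrg_table$timepoint, mean)[cfg$timepoints]
round(100 * rrg_mean, 1)
#>   0h   1h   2h   4h   8h  18h
#> 17.9 19.8 20.4 24.2 30.5 34.1

rc18 <- res$rc_table[res$rc_table$timepoint == "18h", ]
round(100 * max(rc18$rc_pct), 1)
#> [1] 57.5
```

Reading the numbers: the DEG superset is dominated by truly responsive
genes, induced most strongly at the late timepoints. Mean RRG starts
nonzero in vehicle cells (17.9% here) — thresholding at one SD necessarily
calls ~16% of expressing cells "responding" under a null — and climbs
monotonically with treatment duration as the per-cell responder
probability rises; the most responsive gene responds in 57.5% of 18 h
cells. The same qualitative picture (baseline false-call rate ~12%, mean
treated RRG of ~20–30%, monotone increase to the last timepoint) is what
the analysis is designed to expose.

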