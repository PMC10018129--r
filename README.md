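# plasticitome

Rank-based gene-plasticity analysis for immune-cell transcriptomes: an R
package for scoring how variable ("plastic") each gene's expression is
across conditions, discovering the correlated and mutually exclusive gene
programs attached to highly plastic marker genes, and reasoning about the
combinatorial immunophenotypes those markers span.

## Who this is for

Immunologists and computational biologists working with compendia of bulk
microarray / RNA-Seq profiles of sorted immune cells (B cells, CD4+ and
CD8+ T cells, NK cells, monocytes) and matching single-cell UMI data, who
want to evaluate candidate marker genes, predict which phenotypes can
coexist, and stress-test the whole workflow on synthetic data with known
ground truth.

## The model

Expression values are first made platform-comparable by within-sample
**percentile rank scores**:

- RNA-Seq: `P = n / N * 100`, where `N` is the number of genes with
  nonzero TPM in the sample and `n` the ascending ordinal rank; genes with
  zero count are fixed at `P = 0`. TPM is computed as
  `TPM_g = (c_g / l_g) / sum_j (c_j / l_j) * 1e6`.
- Microarray: signals are sorted ascending and divided into 100 equal
  parts scored 1..100 (`ceiling(i * 100 / N)`), ties sharing their mean
  score.

Per-gene plasticity statistics across `n` samples:

- **ARS** (average rank score) `= (1/n) * sum_i P_i` — a rank-scale
  average expression level;
- **GPL (iqr)** `= Q3 − Q1` of the rank scores;
- **GPL (absolute)** `= P(max) − P(min)`, bounded by 100 — the headline
  plasticity score.

**Virtual sorting** dissects a highly plastic target gene (absolute GPL
≥ 50 on both platforms): samples are split into target-high (`g1`) and
target-low (`g2`) groups by exact one-dimensional 2-means, every other
gene gets a delta score `δ_i = ARS_i(g1) − ARS_i(g2)`, and

- **correlated** (cophenotype) genes satisfy `δ ≥ 20` and Pearson
  `r ≥ 0.5`;
- **anticorrelated** (mutually exclusive) genes satisfy `δ ≤ −10`,
  `r < 0` and cosine similarity ≤ 0.1.

Companion statistics: the **coexistence rate** `(C_PP + C_AA) / N` of a
gene pair over detection calls or TPM cutoffs with **APA rate**
`1 − coexistence`; the single-cell **PP rate** (fraction of cells with
both UMI counts > 0); a **polarized-gene screen** (absolute GPL ≥ 50 and
maximum rank ≥ 90 on both platforms); a preranked **enrichment statistic**
for marker sets against the GPL ranking; and an **immunophenotype
grammar** that parses strings such as `CD4+FOXP3+CD25hi` into phenotypic
units, normalizes aliases (CD26 → DPP4), splits phenotypes into layer-k
children and enumerates the `2^n` expression states of a gene
combination.

## Worked example

Everything below runs on synthetic data with planted truth — no
downloads. The generator plants housekeeping, silent and background
genes plus 5 driver genes, each carrying 20 correlated and 20
anticorrelated partner genes tied to the driver's on/off state.

```r
library(plasticitome)

cfg  <- synthetic_config(seed = 7L)
bulk <- generate_bulk(cfg)

ranks_rna <- rank_matrix(bulk$rnaseq, bulk$lengths)
ranks_arr <- rank_matrix(bulk$array)
merged <- merge_platforms(gene_stats_table(ranks_arr),
                          gene_stats_table(ranks_rna))
round(merged$ars_pearson, 4)
#> [1] 0.9496

pol <- screen_polarized(merged)          # GPL >= 50 & max rank >= 90, both platforms
length(pol); sum(bulk$truth$drivers %in% pol)
#> [1] 205
#> [1] 5

v <- virtual_sort("DRV001", ranks_rna)
v
#> VirtualSortResult for DRV001: 20 correlated, 20 anticorrelated (g1 n=30, g2 n=30)
head(v$table, 5)
#>         gene     delta    pearson     cosine          class
#> 205 COR1_001  83.52719  0.9419182 0.97044555     correlated
#> 311 ANT1_007 -83.25138 -0.9471882 0.01011110 anticorrelated
#> 209 COR1_005  82.68761  0.9283547 0.96355832     correlated
#> 217 COR1_013  82.34482  0.9677726 0.98355964     correlated
#> 310 ANT1_006 -82.16736 -0.9472498 0.00769148 anticorrelated

sc <- generate_singlecell(cfg, bulk$truth)
ev <- evaluate_vsort_sc(v, sc$sc)
```

The ARS correlation of 0.95 says the two platforms agree on average
expression after rank normalization. The screen recovers all 5 planted
drivers among 205 polarized genes (driver partners are polarized by
construction). Virtual sorting calls exactly the planted 20 + 20 partner
genes of `DRV001`; in the matched single-cell data the correlated set
keeps a higher Pearson correlation (median 0.455 vs −0.460) and PP rate
(median 0.238 vs 0.003) than the anticorrelated set, the expected
single-cell signature of the bulk result.

The immunophenotype grammar works standalone:

```r
p <- parse_phenotype("CD4+FOXP3+CD25hi")
sapply(split_layers(p, 2), format)
#> [1] "CD4+FOXP3+"   "CD4+CD25hi"   "FOXP3+CD25hi"
length(enumerate_states(c("CCR7", "DPP4", "ITGA6")))
#> [1] 8
```

`run_pipeline(run_config(outdir, seed = 7L))` chains all stages
(simulate → rank → plasticity → screen → vsort → coexist → phen → gsea)
and writes per-stage TSVs plus a JSON run manifest.

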