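---
title: "Gene plasticity methods: models, conventions and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene plasticity methods: models, conventions and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasticitome)
```

## The problem

Immune-cell subsets are defined by marker-gene combinations
(immunophenotypes such as `CD45RA+CCR7-`). A gene is useful as a marker
precisely when its expression is *plastic* — high under some conditions,
low or absent under others — so that it can split a cell population into
subsets. This package quantifies plasticity from compendia of bulk
expression profiles, finds the gene programs that travel with a plastic
marker, and manipulates the combinatorics of the phenotypes those markers
define.

## Percentile rank normalization

Microarray signal and RNA-Seq TPM are not directly comparable. Both are
reduced to within-sample percentile rank scores in [0, 100]:

* RNA-Seq / TPM / UMI: nonzero values are ranked ascending and scaled as
  `P = n/N * 100` with `N` the number of nonzero values. Zeros are fixed
  at `P = 0`, which encodes "not detected" as an absolute floor: a gene
  with a zero count in one assay and an untied maximum in another attains
  the largest possible absolute plasticity score of 100.
* Arrays have no reliable zero, so all `N` genes are sorted ascending and
  scored `ceiling(i * 100 / N)` — 100 equal parts labelled 1..100.

**Tie convention.** The ordinal-rank formula is undefined under ties. Tied
values receive the mean of their ordinal scores (fractional ranks
allowed). This makes both rank transforms permutation-invariant and
deterministic; it is the only tie rule under which random input order
cannot change results.

Rank scores are invariant under any strictly increasing transform of the
input, so all downstream statistics depend only on within-sample
orderings.

## Plasticity scores

For a gene with rank scores `P_1..P_n` across `n` samples:

* `ARS = mean(P_i)` — average expression on the rank scale;
* `GPL(iqr) = Q3 - Q1`;
* `GPL(abs) = max(P) - min(P)`, in [0, 100].

**Quartile convention.** The quartiles use linear interpolation between
order statistics (R's default type 7). No convention is canonical for
these scores; the absolute GPL, which anchors every downstream threshold
in this package, is convention-free.

`GPL(abs)` is monotone under adding samples — enlarging the condition set
can only reveal more plasticity, never less — which the test suite
asserts as a property. The corollary is that plasticity estimates are
relative to the breadth of conditions sampled.

## Sample quality control

RNA-Seq samples pass when protein-coding genes contribute at least
500,000 reads, strictly more than 50% of all reads, and at least 10,000
protein-coding genes are detected (`qc_thresholds()`). The strict ">"
on the fraction and inclusive ">=" on the two counts follow the stated
screening rules exactly. Marker-based QC (`marker_qc()`) additionally
requires each lineage marker (e.g. CD79A/CD79B for B cells) to rank at or
above `marker_rank_min` in every kept sample; no published cutoff exists
for this rank floor, so the default of 70 is this package's documented
choice — high enough that a lineage marker is clearly expressed, low
enough to tolerate rank jitter in deep profiles.

## Virtual sorting

Given a highly plastic target gene, samples are split into a target-high
group `g1` and target-low group `g2`. Because the values are
one-dimensional, the 2-means partition is solved *exactly* by scanning
the n−1 cuts in sorted order for the minimal within-cluster sum of
squares — no random initialization, no seed, and a brute-force oracle
over all bipartitions confirms optimality in the tests.

Each gene then receives `delta_i = ARS_i(g1) - ARS_i(g2)`, plus a
Pearson correlation and a cosine similarity against the target across
all samples. Filters: correlated genes need `delta >= 20` and
`r >= 0.5`; anticorrelated genes need `delta <= -10`, `r < 0` and
cosine ≤ 0.1. The asymmetric delta bounds reflect that negative markers
are empirically harder to find. Cosine similarity on non-negative
vectors lives in [0, 1] and measures co-occurrence rather than linear
association — the anticorrelated relationship is intrinsically
nonlinear (the partner is *absent* when the target is high), which is
why it is filtered with cosine and a sign constraint instead of a strong
negative correlation.

**Metric space.** Pearson, cosine and the 2-means split operate on
percentile-rank vectors by default (`metric_space = "rank"`), the
platform-comparable representation used everywhere else; raw values are
supported as an option. A zero vector has cosine similarity defined as 0
with a warning (a never-expressed gene is vacuously exclusive). The
target is excluded from its own partner lists.

## Coexistence statistics

For a gene pair over `N` samples, `coexistence = (C_PP + C_AA) / N` and
`APA = 1 - coexistence`, with presence taken from detection calls
(arrays) or `TPM >= cutoff` (RNA-Seq; the cutoff series 1, 2, 3, 4, 5,
10, 20 is emitted side by side since no single value is canonical). In
single-cell data the PP rate is the fraction of cells with both UMI
counts positive; it is bounded by each gene's expressed fraction, and the
25% expressed-fraction screen identifies genes in a high-plasticity
state within a dataset. The comparison of correlated vs anticorrelated
distributions in `evaluate_vsort_sc()` uses a one-sided Wilcoxon
rank-sum test, reported descriptively (the claim of interest is the
direction of the medians, not a calibrated inference).

## Immunophenotype grammar

A phenotype string is a concatenation of units, each a marker token
followed by an expression tag from the closed vocabulary `+`, `-`, `hi`,
`lo`, `int`, `bright`, `dim`, `mid`, `medium`, `high`. Parsing takes, at
each position, the shortest marker followed by a tag that lets the rest
of the string parse, matching tags longest-first (`CD26high` is
`CD26`+`high`, not `CD26`+`hi`+junk). Graded tags stay distinct at parse
time; state *enumeration* is binary (`+`/`-`) because a plastic gene
contributes two functional states — high and low/no expression — so `n`
genes span `2^n` phenotypes.

An ASCII hyphen is genuinely ambiguous: `CD45RA-CCR7+` uses it as a
negative tag, `HLA-DR+` as part of a marker name. The default reading is
the negative tag; supplying an alias table lets known marker names
(matched longest-first, case-insensitively) win, which resolves `HLA-DR`
correctly. Unicode minus and en-dash are normalized to `-` before
parsing. Alias normalization maps markers to standard symbols
(CD26 → DPP4), merges duplicate units and rejects contradictory tags on
one symbol; it is idempotent. Deduplication uses a canonical key — units
sorted by (symbol, tag) — so writing order never matters. Layer-k
children of an n-unit phenotype are its `choose(n, k)` unit subsets;
corpus statistics deduplicate children globally by canonical key (the
natural reading when counting distinct marker combinations in a
literature corpus).

Candidate extraction from plain text uses windowed regular expressions of
the form `.{0,20}[+-].{0,12}[TB].{0,12}cell`, extended with the graded
label vocabulary. Species assignment of mined phenotypes is metadata
supplied by the user, not inferred.

## Preranked enrichment

Marker sets are tested against the gene list ranked by descending
absolute GPL with the weighted Kolmogorov–Smirnov running-sum statistic
(weight 1 by default; weight 0 gives the symmetric unweighted form used
by the reversal-invariance tests). The null resamples random gene sets of
the same size — the only permutation scheme available for preranked
input. NES divides the observed ES by the mean |ES| of same-signed null
scores; the p-value is add-one corrected. On lists small enough to
enumerate, the permutation p-value is checked against the exhaustive
null, and the statistic itself is cross-checked against an independent
implementation.

## Synthetic data: what it emulates

`generate_bulk()` / `generate_singlecell()` plant a known truth that
every pipeline stage must recover:

* **Drivers** (5) toggle between an off state (mean 0.05 on a TPM-like
  scale) and an on state 20,000-fold higher (1000) per sample
  (`driver_on_fraction = 0.5`). The large fold mirrors genuinely bipolar
  marker genes — silent below detection in one state, strongly expressed
  in the other; it is what places drivers above the housekeeping band
  when on (hence max rank ≥ 90) and at rank 0 when off.
* **Correlated / anticorrelated members** (20 + 20 per driver) are high
  exactly when their driver is on / off.
* **Housekeeping** genes (100) have gene-specific means in a log-normal
  band around 500 (identical means would maximize rank jostling and
  overstate their plasticity); **silent** genes (100) sit at 0.02;
  **background** genes (100) have stable means spanning the dynamic
  range log-uniformly.
* Arrays add log-normal measurement noise (sd 0.25 on the natural-log
  scale) with detection calls above a noise floor of 1; RNA-Seq draws
  negative-binomial counts (dispersion 0.05, the scale of sorted-
  population bulk data) with gene lengths 500–5000 bp; single cells
  inherit the same state model per cell, scaled to ~5000 expected UMIs,
  with independent Bernoulli dropout (rate 0.3) producing the
  characteristic zero inflation.

One latent truth drives both bulk platforms and the single-cell matrix,
so cross-platform and cross-modality consistency checks are meaningful.
All sampling is seeded; identical configs reproduce identical data.

**What it does not emulate:** batch effects, library-size confounding,
doublets, correlated dropout, or real marker biology. Passing recovery
tests therefore demonstrates that the algorithms are correct and
well-calibrated under the stated generative model — not that real
compendia satisfy that model.

**Rank-space caveats discovered during validation.** Percentile ranks
are a compositional scale: a housekeeping gene's rank moves when other
genes toggle in and out of the detected set, so even noise-free
housekeeping genes show a few points of absolute GPL on RNA-Seq, and
genes sharing a mean exchange ranks freely (why the generator gives each
housekeeping gene its own mean). Similarly, an array rank cannot fall
below the fraction of genes beneath the off state, so array GPL for
drivers tops out near 60–70 rather than 100 — the tests assert these
attainable bounds rather than idealized ones.

## Problem sizes and numerical choices

Tests and the acceptance suite run the generator at its default
conditions (60 samples, ~445 genes, 300 cells; 20 seeds for recovery
statistics), sizes at which every planted effect is comfortably
identifiable and the whole suite completes in under a minute on one
CPU. Degenerate inputs are errors, not silent
defaults: constant target vectors (no 2-means split), all-zero count
vectors (TPM undefined), empty gene-set intersections, phenotype strings
without a complete marker+tag segmentation. Ties are broken
deterministically everywhere (mean ranks; lexicographic probe and gene
identifiers), so no result depends on input order.

## Known limitations

* Plasticity is relative to the sampled conditions; the scores say
  nothing about conditions not represented in the compendium.
* Probe-set collapse keeps the probe with the largest mean across all
  samples (ties to the lexicographically smallest probe id) — a single
  coherent gene row, at the cost of ignoring probe-level
  sample-specificity.
* The anticorrelated filters presuppose that "off" means undetected; in
  data where the low state remains well above detection, the cosine
  filter loses its discriminating power.
* Imputation of single-cell dropouts is out of scope; an imputed matrix
  can be supplied as a second input to `evaluate_vsort_sc()`.
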