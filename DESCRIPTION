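Package: plasticitome
Title: Gene Plasticity Scoring, Virtual Sorting and Immunophenotype
    Combinatorics for Immune-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rank-based analysis of gene expression plasticity across bulk
    (microarray and RNA-Seq) and single-cell transcriptomes. Expression
    values are converted to within-sample percentile rank scores; per-gene
    plasticity is summarised by the average rank score (ARS) and by
    interquartile and absolute gene plasticity (GPL) scores. Highly plastic
    genes are dissected by virtual sorting (in silico cell sorting): samples
    are split into high/low groups by exact one-dimensional 2-means on the
    target gene, and correlated (cophenotype) and anticorrelated (mutually
    exclusive) genes are called from delta average-rank differences with
    Pearson and cosine similarity filters. Companion tools compute
    coexistence and absent-present (APA) rates from detection calls, TPM
    cutoffs or single-cell UMI counts, parse and enumerate combinatorial
    immunophenotype strings (marker plus expression tag), score marker sets
    by preranked enrichment against the GPL ranking, and simulate bulk and
    single-cell datasets with planted plasticity structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
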