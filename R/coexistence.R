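coexist_from_present <- function(pa, pb, method, cutoff = NULL) {
  n <- length(pa)
  c_pp <- sum(pa & pb)
  c_aa <- sum(!pa & !pb)
  c_pa <- sum(pa & !pb)
  c_ap <- sum(!pa & pb)
  rate <- (c_pp + c_aa) / n
  structure(list(counts = list(c_pp = c_pp, c_aa = c_aa, c_pa = c_pa,
                               c_ap = c_ap, n = n),
                 coexistence_rate = rate,
                 apa_rate = 1 - rate,
                 method = method,
                 cutoff = cutoff),
            class = "CoexistenceResult")
}

#' @export
print.CoexistenceResult <- function(x, ...) {
  cat(sprintf("CoexistenceResult [%s%s]: coexistence %.4f, APA %.4f (n=%d)\n",
              x$method,
              if (!is.null(x$cutoff)) paste0(", cutoff ", x$cutoff) else "",
              x$coexistence_rate, x$apa_rate, x$counts$n))
  invisible(x)
}

#' Coexistence rate from detection calls
#'
#' `coexistence = (C_PP + C_AA) / N`: the fraction of samples in which a
#' gene pair is both present or both absent according to microarray
#' detection calls. The APA (absent-present + present-absent) rate is
#' `1 - coexistence` and measures mutually exclusive expression.
#'
#' @param callsA,callsB Aligned per-sample vectors over `{"P","A"}`.
#' @return A `CoexistenceResult`: counts, `coexistence_rate`, `apa_rate`.
#' @export
coexist_calls <- function(callsA, callsB) {
  if (length(callsA) != length(callsB)) stop("call vectors must align")
  if (length(callsA) == 0L) stop("empty call vectors")
  if (!all(c(callsA, callsB) %in% c("P", "A")))
    stop("calls must be 'P' or 'A'")
  coexist_from_present(callsA == "P", callsB == "P", "calls")
}

#' Coexistence rate from TPM values at a cutoff
#'
#' A gene is called present in a sample when its TPM is greater than or
#' equal to `cutoff`; coexistence is then counted as in [coexist_calls()].
#' Typical cutoffs: 1, 2, 3, 4, 5, 10, 20.
#'
#' @param tpmA,tpmB Aligned per-sample TPM vectors.
#' @param cutoff Positive presence threshold.
#' @return A `CoexistenceResult`.
#' @export
coexist_tpm <- function(tpmA, tpmB, cutoff) {
  if (length(tpmA) != length(tpmB)) stop("TPM vectors must align")
  if (length(tpmA) == 0L) stop("empty TPM vectors")
  if (cutoff <= 0) stop("cutoff must be positive")
  coexist_from_present(tpmA >= cutoff, tpmB >= cutoff, "tpm-cutoff", cutoff)
}

#' Single-cell present-present rate
#'
#' Fraction of cells in which both genes of a pair have UMI count
#' simultaneously larger than zero.
#'
#' @param umiA,umiB Aligned per-cell UMI count vectors.
#' @return PP rate in `[0, 1]`.
#' @export
sc_pp_rate <- function(umiA, umiB) {
  if (length(umiA) != length(umiB)) stop("UMI vectors must align")
  if (length(umiA) == 0L) stop("empty UMI vectors")
  mean(umiA > 0 & umiB > 0)
}

#' Fraction of cells expressing a gene
#'
#' Proportion of cells with UMI count above zero; the screening statistic
#' behind the "25% of single cells with detectable expression" filter.
#'
#' @param m An [ExpressionMatrix] with platform `sc-umi`.
#' @param gene Gene identifier.
#' @return Expressed fraction in `[0, 1]`.
#' @export
expressed_fraction <- function(m, gene) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!gene %in% rownames(m$values))
    stop("gene '", gene, "' not in the matrix")
  mean(m$values[gene, ] > 0)
}

#' Evaluate virtual-sorting output in single-cell data
#'
#' For each correlated and anticorrelated gene of a virtual-sorting result,
#' computes the Pearson correlation and the present-present rate against
#' the target across cells of a UMI matrix, and summarises whether the
#' correlated set exceeds the anticorrelated set (median difference and
#' one-sided Wilcoxon rank-sum p-values, reported descriptively).
#'
#' @param v A `VirtualSortResult`.
#' @param m An [ExpressionMatrix] with platform `sc-umi` containing the
#'   target; member genes absent from the matrix are dropped and listed.
#' @param imputed Optional second matrix (e.g. expression-recovered values)
#'   evaluated the same way and reported under `$imputed`.
#' @return List with `per_gene` (data.frame: gene, class, pearson, pp_rate),
#'   `summary` (medians, differences, p-values), `dropped`, and optionally
#'   `imputed`.
#' @export
evaluate_vsort_sc <- function(v, m, imputed = NULL) {
  stopifnot(inherits(v, "VirtualSortResult"), inherits(m, "ExpressionMatrix"))
  if (!v$target %in% rownames(m$values))
    stop("target gene '", v$target, "' not in the single-cell matrix")
  corr <- setdiff(intersect(v$correlated, rownames(m$values)), v$target)
  anti <- setdiff(intersect(v$anticorrelated, rownames(m$values)), v$target)
  dropped <- setdiff(c(v$correlated, v$anticorrelated), c(corr, anti))
  if (length(corr) == 0L || length(anti) == 0L)
    stop("a gene class is empty after intersecting with the matrix")
  tv <- m$values[v$target, ]
  eval_set <- function(genes, cls) {
    data.frame(gene = genes, class = cls,
               pearson = vapply(genes, function(g)
                 suppressWarnings(stats::cor(m$values[g, ], tv)),
                 numeric(1L)),
               pp_rate = vapply(genes, function(g)
                 sc_pp_rate(m$values[g, ], tv), numeric(1L)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  per_gene <- rbind(eval_set(corr, "correlated"),
                    eval_set(anti, "anticorrelated"))
  pc <- per_gene$pearson[per_gene$class == "correlated"]
  pa <- per_gene$pearson[per_gene$class == "anticorrelated"]
  rc <- per_gene$pp_rate[per_gene$class == "correlated"]
  ra <- per_gene$pp_rate[per_gene$class == "anticorrelated"]
  wil <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y,
                                        alternative = "greater")$p.value)
  }
  summary <- list(
    median_pearson_correlated = stats::median(pc, na.rm = TRUE),
    median_pearson_anticorrelated = stats::median(pa, na.rm = TRUE),
    median_pp_correlated = stats::median(rc),
    median_pp_anticorrelated = stats::median(ra),
    pearson_direction_supported =
      stats::median(pc, na.rm = TRUE) > stats::median(pa, na.rm = TRUE),
    pp_direction_supported = stats::median(rc) > stats::median(ra),
    p_pearson = wil(pc, pa),
    p_pp = wil(rc, ra))
  out <- list(per_gene = per_gene, summary = summary, dropped = dropped)
  if (!is.null(imputed))
    out$imputed <- evaluate_vsort_sc(v, imputed)[c("per_gene", "summary")]
  out
}
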