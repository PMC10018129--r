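#' Average rank score
#'
#' The ARS of a gene is the arithmetic mean of its percentile rank scores
#' over all samples: a rank-scale average expression level.
#'
#' @param ranks Per-sample rank-score vector for one gene.
#' @return The mean rank score.
#' @export
ars <- function(ranks) {
  if (length(ranks) == 0L) stop("empty rank vector")
  mean(ranks)
}

#' Interquartile gene plasticity score
#'
#' `GPL(iqr) = Q3 - Q1` of a gene's rank scores, with quartiles computed by
#' linear interpolation between order statistics (R's default type-7
#' convention).
#'
#' @param ranks Per-sample rank-score vector, length >= 2.
#' @return GPL score in `[0, 100]`.
#' @export
gpl_iqr <- function(ranks) {
  if (length(ranks) < 2L) stop("at least two samples required for GPL (iqr)")
  q <- stats::quantile(ranks, c(0.25, 0.75), names = FALSE, type = 7)
  q[2L] - q[1L]
}

#' Absolute gene plasticity score
#'
#' `GPL(abs) = P(max) - P(min)` over a gene's rank scores; the largest
#' attainable score is 100 (rank 0 in some sample and rank 100 in another).
#'
#' @param ranks Per-sample rank-score vector.
#' @return GPL score in `[0, 100]`.
#' @export
gpl_abs <- function(ranks) {
  if (length(ranks) == 0L) stop("empty rank vector")
  max(ranks) - min(ranks)
}

#' Per-gene plasticity statistics for a rank matrix
#'
#' @param r A [RankMatrix].
#' @return data.frame with one row per gene: `gene`, `ars`, `q1`, `q3`,
#'   `gpl_iqr`, `gpl_abs`, `rank_min`, `rank_max`, `n_samples`, `platform`.
#'   With a single sample both GPL scores are 0.
#' @export
gene_stats_table <- function(r) {
  stopifnot(inherits(r, "RankMatrix"))
  v <- r$values
  n <- ncol(v)
  if (n >= 2L) {
    q <- apply(v, 1L, stats::quantile, probs = c(0.25, 0.75), names = FALSE,
               type = 7)
    q1 <- q[1L, ]
    q3 <- q[2L, ]
  } else {
    q1 <- q3 <- v[, 1L]
  }
  rmin <- apply(v, 1L, min)
  rmax <- apply(v, 1L, max)
  data.frame(gene = rownames(v),
             ars = rowMeans(v),
             q1 = q1, q3 = q3,
             gpl_iqr = q3 - q1,
             gpl_abs = rmax - rmin,
             rank_min = rmin, rank_max = rmax,
             n_samples = n,
             platform = r$platform,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Merge per-gene statistics from two platforms
#'
#' Inner join of array and RNA-Seq [gene_stats_table()] outputs on the gene
#' identifier; only genes measured on both platforms are kept. Also reports
#' the Pearson correlation of the paired ARS values, the cross-platform
#' comparability check.
#'
#' @param a,b data.frames from [gene_stats_table()] (conventionally array
#'   first, RNA-Seq second).
#' @param suffixes Column suffixes for the two platforms.
#' @return List with `stats` (merged data.frame, columns suffixed) and
#'   `ars_pearson`.
#' @export
merge_platforms <- function(a, b, suffixes = c("_array", "_rnaseq")) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty statistics table")
  m <- merge(a, b, by = "gene", suffixes = suffixes)
  if (nrow(m) == 0L) stop("no genes shared between the two platforms")
  list(stats = m[order(m$gene), , drop = FALSE],
       ars_pearson = stats::cor(m[[paste0("ars", suffixes[1L])]],
                                m[[paste0("ars", suffixes[2L])]]))
}

#' Screen for polarized genes
#'
#' Polarized genes are highly plastic on both platforms (`gpl_abs >=
#' gpl_min` on both) and capable of extreme high expression (`rank_max >=
#' rankmax_min` on both), i.e. they reach the top decile of expression
#' under some condition.
#'
#' @param merged Result of [merge_platforms()] (or its `stats` element).
#' @param gpl_min Absolute GPL floor, default 50.
#' @param rankmax_min Maximum-rank floor, default 90.
#' @return Character vector of selected gene identifiers.
#' @export
screen_polarized <- function(merged, gpl_min = 50, rankmax_min = 90) {
  m <- if (is.data.frame(merged)) merged else merged$stats
  sel <- m$gpl_abs_array >= gpl_min & m$gpl_abs_rnaseq >= gpl_min &
    m$rank_max_array >= rankmax_min & m$rank_max_rnaseq >= rankmax_min
  m$gene[sel]
}

#' Fraction of marker genes that are highly plastic
#'
#' Of a marker-gene set, the share whose absolute GPL score reaches
#' `cutoff` on either (or both) platform(s). Markers absent from the merged
#' statistics are excluded from numerator and denominator and listed.
#'
#' @param markers Character vector of marker gene symbols.
#' @param merged Result of [merge_platforms()] (or its `stats` element).
#' @param cutoff Absolute GPL cutoff, default 50.
#' @param mode `"either"` (default) or `"both"` platform requirement.
#' @return List: `fraction` in `[0,1]`, `percent`, `n` (numerator), `total`
#'   (denominator), `missing` (markers not measured).
#' @export
marker_plastic_fraction <- function(markers, merged, cutoff = 50,
                                    mode = c("either", "both")) {
  mode <- match.arg(mode)
  if (length(markers) == 0L) stop("empty marker set")
  m <- if (is.data.frame(merged)) merged else merged$stats
  missing <- setdiff(markers, m$gene)
  present <- m[m$gene %in% markers, , drop = FALSE]
  hit <- if (mode == "either")
    pmax(present$gpl_abs_array, present$gpl_abs_rnaseq) >= cutoff
  else
    pmin(present$gpl_abs_array, present$gpl_abs_rnaseq) >= cutoff
  n <- sum(hit)
  total <- nrow(present)
  list(fraction = if (total > 0L) n / total else NaN,
       percent = if (total > 0L) n / total * 100 else NaN,
       n = n, total = total, missing = missing)
}
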