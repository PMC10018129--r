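#' Virtual-sorting filter parameters
#'
#' Defaults follow the published operating point: delta >= 20 for
#' correlated genes, delta <= -10 for anticorrelated genes (negative
#' markers are harder to find, hence the asymmetric bound), Pearson >= 0.5
#' for correlated, Pearson strictly below 0 together with cosine similarity
#' <= 0.1 for anticorrelated.
#'
#' @param delta_pos_min,delta_neg_max,pearson_min_corr,pearson_max_anti,cosine_max_anti
#'   See description.
#' @return Named list of parameters.
#' @export
vsort_params <- function(delta_pos_min = 20, delta_neg_max = -10,
                         pearson_min_corr = 0.5, pearson_max_anti = 0,
                         cosine_max_anti = 0.1) {
  stopifnot(delta_pos_min > 0, delta_neg_max < 0,
            pearson_min_corr >= -1, pearson_min_corr <= 1,
            pearson_max_anti >= -1, pearson_max_anti <= 1,
            cosine_max_anti >= 0, cosine_max_anti <= 1)
  list(delta_pos_min = delta_pos_min, delta_neg_max = delta_neg_max,
       pearson_min_corr = pearson_min_corr,
       pearson_max_anti = pearson_max_anti,
       cosine_max_anti = cosine_max_anti)
}

#' Exact one-dimensional 2-means split
#'
#' Partitions samples into two groups by the target gene's expression,
#' minimizing the within-cluster sum of squares. In one dimension the
#' optimal 2-partition is a cut in sorted order, so the optimum is found by
#' scanning all cuts; no random initialization is involved. The group with
#' the higher mean is labelled `g1` (the positive/high group).
#'
#' @param values Per-sample expression (or rank) vector for the target
#'   gene; at least two distinct values.
#' @return Character vector over `{"g1","g2"}` aligned with `values`.
#' @export
kmeans2_split <- function(values) {
  n <- length(values)
  if (n < 2L) stop("at least two samples required")
  if (length(unique(values)) < 2L)
    stop("gene not plastic in these samples (constant expression)")
  if (n < 4L)
    warning("fewer than 4 samples: the 2-means split is fragile")
  o <- order(values)
  x <- values[o]
  # WSS of a contiguous segment via prefix sums
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_wss <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  wss <- vapply(seq_len(n - 1L),
                function(k) seg_wss(1L, k) + seg_wss(k + 1L, n),
                numeric(1L))
  k <- which.min(wss)
  labels <- character(n)
  labels[o[seq_len(k)]] <- "g2"       # lower cluster
  labels[o[(k + 1L):n]] <- "g1"       # higher cluster
  names(labels) <- names(values)
  labels
}

#' Delta scores between the two virtual-sorting groups
#'
#' `delta_i = ARS_i(g1) - ARS_i(g2)`: the difference of each gene's average
#' rank score between the target-high and target-low sample groups.
#'
#' @param r A [RankMatrix].
#' @param labels Per-sample labels over `{"g1","g2"}` aligned with the
#'   columns of `r`.
#' @return Named numeric vector of delta values in `[-100, 100]`.
#' @export
delta_scores <- function(r, labels) {
  stopifnot(inherits(r, "RankMatrix"))
  if (length(labels) != ncol(r$values))
    stop("labels must align with samples")
  g1 <- labels == "g1"
  g2 <- labels == "g2"
  if (!any(g1) || !any(g2)) stop("both groups must be non-empty")
  rowMeans(r$values[, g1, drop = FALSE]) -
    rowMeans(r$values[, g2, drop = FALSE])
}

#' Cosine similarity of two non-negative vectors
#'
#' `dot(x, y) / (||x|| ||y||)`, ranging from 0 (orthogonal, mutually
#' exclusive expression) to 1 (parallel). If either vector is all zero the
#' similarity is defined as 0 with a warning (a never-expressed gene is
#' vacuously exclusive).
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Cosine similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("vectors must be non-negative")
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("zero vector: cosine similarity defined as 0")
    return(0)
  }
  sum(x * y) / (nx * ny)
}

#' Virtual sorting of a highly plastic target gene
#'
#' Splits samples into target-high (`g1`) and target-low (`g2`) groups by
#' exact 1-D 2-means on the target's values, computes every gene's delta
#' score, Pearson correlation and cosine similarity against the target
#' (across all samples, on rank scores by default), and calls:
#' correlated genes with `delta >= delta_pos_min` and
#' `pearson >= pearson_min_corr`; anticorrelated genes with
#' `delta <= delta_neg_max`, `pearson < pearson_max_anti` and
#' `cosine <= cosine_max_anti`. The target itself is excluded from both
#' lists, which are ordered by `|delta|` descending.
#'
#' @param target Target gene identifier (should be highly plastic,
#'   conventionally `gpl_abs >= 50` on both platforms).
#' @param r A [RankMatrix] (default metric space) or, with
#'   `metric_space = "raw"`, an [ExpressionMatrix] whose values are used
#'   directly.
#' @param params A [vsort_params()] list.
#' @param metric_space `"rank"` (default) or `"raw"`.
#' @return Object of class `VirtualSortResult`: list with `target`,
#'   `group_labels`, `table` (gene, delta, pearson, cosine, class),
#'   `correlated`, `anticorrelated`, `warnings`.
#' @export
virtual_sort <- function(target, r, params = vsort_params(),
                         metric_space = c("rank", "raw")) {
  metric_space <- match.arg(metric_space)
  vals <- r$values
  if (!target %in% rownames(vals))
    stop("target gene '", target, "' not in the matrix")
  tv <- vals[target, ]
  labels <- kmeans2_split(tv)
  warnings <- character()
  if (min(table(labels)) < 2L) {
    warnings <- c(warnings, "fewer than 2 samples in one group")
    warning("fewer than 2 samples in one group")
  }
  g1 <- labels == "g1"
  delta <- rowMeans(vals[, g1, drop = FALSE]) -
    rowMeans(vals[, !g1, drop = FALSE])
  pearson <- suppressWarnings(as.vector(stats::cor(t(vals), tv)))
  names(pearson) <- rownames(vals)
  tnorm <- sqrt(sum(tv^2))
  cosine <- if (tnorm == 0) rep(0, nrow(vals)) else {
    num <- as.vector(vals %*% tv)
    den <- sqrt(rowSums(vals^2)) * tnorm
    ifelse(den == 0, 0, num / den)
  }
  names(cosine) <- rownames(vals)

  genes <- setdiff(rownames(vals), target)
  is_corr <- delta[genes] >= params$delta_pos_min &
    !is.na(pearson[genes]) & pearson[genes] >= params$pearson_min_corr
  is_anti <- delta[genes] <= params$delta_neg_max &
    !is.na(pearson[genes]) & pearson[genes] < params$pearson_max_anti &
    cosine[genes] <= params$cosine_max_anti
  cls <- rep("none", length(genes))
  cls[is_corr] <- "correlated"
  cls[is_anti] <- "anticorrelated"
  tab <- data.frame(gene = genes,
                    delta = unname(delta[genes]),
                    pearson = unname(pearson[genes]),
                    cosine = unname(cosine[genes]),
                    class = cls,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$delta), tab$gene), , drop = FALSE]
  structure(list(target = target,
                 group_labels = labels,
                 table = tab,
                 correlated = tab$gene[tab$class == "correlated"],
                 anticorrelated = tab$gene[tab$class == "anticorrelated"],
                 params = params,
                 metric_space = metric_space,
                 warnings = warnings),
            class = "VirtualSortResult")
}

#' @export
print.VirtualSortResult <- function(x, ...) {
  cat(sprintf(
    "VirtualSortResult for %s: %d correlated, %d anticorrelated (g1 n=%d, g2 n=%d)\n",
    x$target, length(x$correlated), length(x$anticorrelated),
    sum(x$group_labels == "g1"), sum(x$group_labels == "g2")))
  invisible(x)
}
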