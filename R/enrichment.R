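#' Ranked gene list for preranked enrichment
#'
#' Genes ordered by descending score (absolute GPL score in the intended
#' use), ties broken by gene identifier ascending so the order is
#' deterministic.
#'
#' @param genes Character vector of unique gene identifiers.
#' @param scores Numeric scores aligned with `genes`.
#' @return Object of class `RankedList`: list with `genes` and `scores`
#'   in list order.
#' @export
ranked_list <- function(genes, scores) {
  if (length(genes) != length(scores)) stop("genes and scores must align")
  if (anyDuplicated(genes)) stop("duplicate genes in ranked list")
  if (anyNA(scores)) stop("missing scores")
  o <- order(-scores, genes)
  structure(list(genes = genes[o], scores = scores[o]),
            class = "RankedList")
}

#' Running enrichment score
#'
#' The weighted Kolmogorov-Smirnov-like running-sum statistic: walking down
#' the ranked list, hits (genes in the set) increment the sum by
#' `|score|^weight` normalized over hit scores, misses decrement by
#' `1 / (N - Nh)`. The enrichment score ES is the maximum deviation from
#' zero (signed); positive ES means the set concentrates at the top of the
#' list.
#'
#' @param l A [ranked_list()].
#' @param s Character vector, the gene set (must intersect the list and
#'   not cover it entirely).
#' @param weight Score weight exponent; 1 (default) is the classic
#'   weighted statistic, 0 the unweighted KS form.
#' @return List with `es` and `running` (per-position running sum) and
#'   `leading_edge` (hits at or before the ES extremum).
#' @export
running_es <- function(l, s, weight = 1) {
  stopifnot(inherits(l, "RankedList"))
  hit <- l$genes %in% s
  nh <- sum(hit)
  n <- length(l$genes)
  if (nh == 0L) stop("gene set does not intersect the ranked list")
  if (nh == n) stop("gene set covers the entire list (degenerate)")
  w <- abs(l$scores)^weight
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) l$genes[seq_len(i_max)][hit[seq_len(i_max)]]
  else l$genes[i_max:n][hit[i_max:n]]
  list(es = es, running = running, leading_edge = leading)
}

#' Preranked enrichment with permutation null
#'
#' Builds the null by resampling random gene sets of the same size from
#' the ranked list, normalizes the enrichment score against same-signed
#' null scores (NES), and reports an add-one-corrected two-sided
#' permutation p-value on `|ES|`.
#'
#' @param l A [ranked_list()].
#' @param s Gene set.
#' @param n_perm Number of permutations, at least 100 (default 1000).
#' @param seed Integer seed for reproducibility.
#' @param weight Passed to [running_es()].
#' @return Object of class `EnrichmentResult`: list with `es`, `nes`,
#'   `p_value`, `n_permutations`, `leading_edge`.
#' @export
nes_pvalue <- function(l, s, n_perm = 1000L, seed = 1L, weight = 1) {
  stopifnot(inherits(l, "RankedList"))
  if (n_perm < 100L) stop("at least 100 permutations required")
  obs <- running_es(l, s, weight)
  nh <- sum(l$genes %in% s)
  n <- length(l$genes)
  w <- abs(l$scores)^weight
  null_es <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, nh)] <- TRUE
      inc <- numeric(n)
      inc[hit] <- w[hit] / sum(w[hit])
      inc[!hit] <- -1 / (n - nh)
      running <- cumsum(inc)
      running[which.max(abs(running))]
    }, numeric(1L))
  })
  same_sign <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  structure(list(es = obs$es, nes = nes, p_value = p,
                 n_permutations = n_perm,
                 leading_edge = obs$leading_edge),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: ES %.4f, NES %.4f, p %.4g (%d permutations)\n",
              x$es, x$nes, x$p_value, x$n_permutations))
  invisible(x)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
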