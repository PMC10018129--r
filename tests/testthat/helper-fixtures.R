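# Small in-code fixtures shared across test files.

toy_expression <- function(platform = "rnaseq-count",
                           values = matrix(c(0, 5, 10, 2, 0, 7),
                                           nrow = 3, byrow = TRUE),
                           genes = c("g1", "g2", "g3"),
                           samples = c("s1", "s2")) {
  dimnames(values) <- list(genes, samples)
  ExpressionMatrix(values, platform)
}

toy_rank_matrix <- function(values, platform = "rnaseq-tpm") {
  if (is.null(dimnames(values)))
    dimnames(values) <- list(paste0("g", seq_len(nrow(values))),
                             paste0("s", seq_len(ncol(values))))
  RankMatrix(values, platform)
}

random_rank_matrix <- function(n_genes, n_samples, platform = "rnaseq-tpm") {
  v <- matrix(stats::runif(n_genes * n_samples, 0, 100), n_genes)
  toy_rank_matrix(v, platform)
}

# A small but structurally complete synthetic configuration used where a
# test does not need the default study conditions.
small_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_samples = 30L, n_cells = 120L, seed = seed,
         housekeeping_high = 30L, silent = 30L, drivers = 2L,
         correlated_per_driver = 10L, anticorrelated_per_driver = 10L,
         noise = 30L),
    list(...))
  do.call(synthetic_config, args)
}

# Exhaustive minimum within-cluster sum of squares over ALL 2-partitions
# (not only sorted-contiguous ones): the brute-force oracle for
# kmeans2_split.
brute_force_min_wss <- function(values) {
  n <- length(values)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    a <- values[grp]
    b <- values[!grp]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wss < best) best <- wss
  }
  best
}

split_wss <- function(values, labels) {
  a <- values[labels == "g1"]
  b <- values[labels == "g2"]
  sum((a - mean(a))^2) + sum((b - mean(b))^2)
}
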