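#' Transcripts per million from raw counts
#'
#' `TPM_g = (counts_g / length_g) / sum_j(counts_j / length_j) * 1e6`. The
#' result always sums to one million.
#'
#' @param counts Named or plain non-negative integer vector of raw read
#'   counts per gene.
#' @param lengths Gene lengths in base pairs: either a vector aligned with
#'   `counts` or a named vector covering every gene in `counts`.
#' @return Numeric vector of TPM values aligned with `counts`.
#' @export
tpm_from_counts <- function(counts, lengths) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(counts)) && !is.null(names(lengths))) {
    missing <- setdiff(names(counts), names(lengths))
    if (length(missing))
      stop("genes without a length: ", paste(missing, collapse = ", "))
    lengths <- lengths[names(counts)]
  }
  if (length(lengths) != length(counts))
    stop("'lengths' must align with 'counts'")
  if (any(lengths < 1)) stop("gene lengths must be >= 1")
  if (all(counts == 0))
    stop("all-zero count vector: TPM normalization undefined")
  rate <- counts / lengths
  tpm <- rate / sum(rate) * 1e6
  names(tpm) <- names(counts)
  tpm
}

#' RNA-Seq sample quality control
#'
#' A sample passes when (i) the total read count over protein-coding genes
#' is at least `min_total_pc_reads`, (ii) protein-coding genes account for
#' strictly more than `min_pc_fraction` of all reads, and (iii) at least
#' `min_detected_pc_genes` protein-coding genes have a nonzero count.
#'
#' @param counts Per-gene raw count vector for one sample.
#' @param is_protein_coding Logical vector aligned with `counts`.
#' @param thresholds A [qc_thresholds()] list.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty when passing).
#' @export
qc_sample <- function(counts, is_protein_coding,
                      thresholds = qc_thresholds()) {
  if (length(counts) == 0L) stop("empty count vector")
  if (length(counts) != length(is_protein_coding))
    stop("'is_protein_coding' must align with 'counts'")
  pc <- counts[is_protein_coding]
  reasons <- character()
  if (sum(pc) < thresholds$min_total_pc_reads)
    reasons <- c(reasons, "total_pc_reads")
  if (!(sum(pc) / sum(counts) > thresholds$min_pc_fraction))
    reasons <- c(reasons, "pc_fraction")
  if (sum(pc > 0) < thresholds$min_detected_pc_genes)
    reasons <- c(reasons, "detected_pc_genes")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Quality-control thresholds
#'
#' Defaults follow the bulk RNA-Seq screening rules: >= 500,000
#' protein-coding reads, protein-coding fraction strictly above 0.5, and
#' >= 10,000 detected protein-coding genes. `marker_rank_min` is the
#' marker-expression rank floor used by [marker_qc()]; no published cutoff
#' exists, 70 is this package's documented default.
#'
#' @param min_total_pc_reads,min_pc_fraction,min_detected_pc_genes,marker_rank_min
#'   See description.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(min_total_pc_reads = 500000L,
                          min_pc_fraction = 0.5,
                          min_detected_pc_genes = 10000L,
                          marker_rank_min = 70) {
  stopifnot(min_total_pc_reads > 0, min_pc_fraction > 0,
            min_pc_fraction <= 1, min_detected_pc_genes > 0,
            marker_rank_min >= 0, marker_rank_min <= 100)
  list(min_total_pc_reads = min_total_pc_reads,
       min_pc_fraction = min_pc_fraction,
       min_detected_pc_genes = min_detected_pc_genes,
       marker_rank_min = marker_rank_min)
}

#' Percentile rank scores for one RNA-Seq sample
#'
#' Zero TPM values are fixed at rank 0. Nonzero values are ranked ascending
#' and scaled as `P = n / N * 100` where `N` is the number of nonzero
#' values and `n` the ordinal rank; tied values share the mean of their
#' ordinal ranks, so the result is permutation-invariant.
#'
#' @param tpm Non-negative per-gene vector (TPM or any monotone equivalent).
#' @return Per-gene rank vector in `[0, 100]`.
#' @export
rank_rnaseq <- function(tpm) {
  if (any(tpm < 0)) stop("negative expression values")
  p <- numeric(length(tpm))
  nz <- tpm > 0
  n_nz <- sum(nz)
  if (n_nz > 0L)
    p[nz] <- rank(tpm[nz], ties.method = "average") / n_nz * 100
  names(p) <- names(tpm)
  p
}

#' Percentile rank scores for one microarray sample
#'
#' Signal values are sorted ascending and divided into 100 equal parts with
#' successive scores 1..100: the value at sorted position `i` of `N` gets
#' `ceiling(i * 100 / N)`. Tied values share the mean score of their tied
#' positions, so the result is permutation-invariant.
#'
#' @param signal Per-gene signal vector (any real values).
#' @return Per-gene rank vector in `[1/N-ish, 100]`, within `[0, 100]`.
#' @export
rank_array <- function(signal) {
  n <- length(signal)
  if (n == 0L) stop("empty signal vector")
  o <- order(signal)
  bucket <- ceiling(seq_len(n) * 100 / n)
  grp <- cumsum(c(TRUE, diff(signal[o]) != 0))
  avg <- stats::ave(bucket, grp, FUN = mean)
  out <- numeric(n)
  out[o] <- avg
  names(out) <- names(signal)
  out
}

#' Percentile-rank normalize an expression matrix
#'
#' Applies [rank_array()] (array signal) or [rank_rnaseq()] (TPM, counts
#' after TPM conversion, or UMI) column-wise.
#'
#' @param m An [ExpressionMatrix].
#' @param lengths Gene lengths, required when `m` holds raw RNA-Seq counts
#'   (each sample is converted to TPM first).
#' @return A [RankMatrix] of the same shape.
#' @export
rank_matrix <- function(m, lengths = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  vals <- m$values
  ranks <- switch(
    m$platform,
    "array-signal" = apply(vals, 2L, rank_array),
    "rnaseq-tpm" = ,
    "sc-umi" = apply(vals, 2L, rank_rnaseq),
    "rnaseq-count" = {
      if (is.null(lengths))
        stop("gene lengths required to rank raw RNA-Seq counts")
      apply(vals, 2L, function(x)
        rank_rnaseq(tpm_from_counts(stats::setNames(x, rownames(vals)),
                                    lengths)))
    })
  rownames(ranks) <- rownames(vals)
  RankMatrix(ranks, m$platform)
}

MARKER_SETS <- list(
  B = c("CD79A", "CD79B"),
  CD4T = c("CD3D", "CD3G", "CD4"),
  CD8T = c("CD3D", "CD3G", "CD8A", "CD8B"),
  NK = c("GNLY", "NKG7"),
  monocyte = c("CD14"))

#' Marker-based sample quality control
#'
#' A sample passes for a declared cell type when every lineage marker gene
#' has rank score at least `marker_rank_min` in that sample. Marker panels:
#' B = CD79A/CD79B; CD4T = CD3D/CD3G/CD4; CD8T = CD3D/CD3G/CD8A/CD8B;
#' NK = GNLY/NKG7; monocyte = CD14.
#'
#' @param r A [RankMatrix].
#' @param cell_type One of `"B"`, `"CD4T"`, `"CD8T"`, `"NK"`, `"monocyte"`.
#' @param thresholds A [qc_thresholds()] list (uses `marker_rank_min`).
#' @return Named logical vector, one entry per sample.
#' @export
marker_qc <- function(r, cell_type, thresholds = qc_thresholds()) {
  stopifnot(inherits(r, "RankMatrix"))
  cell_type <- match.arg(cell_type, names(MARKER_SETS))
  markers <- MARKER_SETS[[cell_type]]
  absent <- setdiff(markers, rownames(r$values))
  if (length(absent))
    stop("marker gene(s) absent from the matrix: ",
         paste(absent, collapse = ", "))
  sub <- r$values[markers, , drop = FALSE]
  apply(sub >= thresholds$marker_rank_min, 2L, all)
}
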