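#' Construct an ExpressionMatrix
#'
#' The central container for bulk and single-cell expression data: a
#' genes-by-samples numeric matrix tagged with its measurement platform and,
#' optionally, a present/absent detection-call matrix of identical shape.
#'
#' @param values Numeric matrix, genes in rows, samples (or cells) in
#'   columns. Row and column names are taken as gene and sample identifiers
#'   unless `gene_ids`/`sample_ids` are given.
#' @param platform One of `"array-signal"`, `"rnaseq-count"`,
#'   `"rnaseq-tpm"`, `"sc-umi"`. Count-like platforms (`rnaseq-count`,
#'   `sc-umi`) must hold integer-valued entries.
#' @param gene_ids,sample_ids Optional character vectors of identifiers;
#'   default to the dimnames of `values`.
#' @param calls Optional character matrix over `{"P","A"}` with the same
#'   shape and axes as `values` (microarray detection calls).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `platform` and `calls`, with identifiers carried as dimnames.
#' @examples
#' m <- matrix(c(0L, 5L, 10L, 2L, 0L, 7L), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' em <- ExpressionMatrix(m, "rnaseq-count")
#' dim(em)
#' @export
ExpressionMatrix <- function(values, platform, gene_ids = NULL,
                             sample_ids = NULL, calls = NULL) {
  platform <- match.arg(platform, PLATFORMS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene and sample identifiers are required (dimnames or arguments)")
  if (anyNA(values)) stop("missing values are not allowed")
  if (any(values < 0)) stop("negative expression values are not allowed")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (platform %in% c("rnaseq-count", "sc-umi") &&
      any(values != round(values)))
    stop("platform '", platform, "' requires integer counts")
  if (!is.null(calls)) {
    if (!identical(dim(calls), dim(values)))
      stop("'calls' must have the same shape as 'values'")
    if (!all(calls %in% c("P", "A")))
      stop("'calls' entries must be 'P' or 'A'")
    dimnames(calls) <- dimnames(values)
  }
  structure(list(values = values, platform = platform, calls = calls),
            class = "ExpressionMatrix")
}

PLATFORMS <- c("array-signal", "rnaseq-count", "rnaseq-tpm", "sc-umi")

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples%s\n",
              x$platform, nrow(x$values), ncol(x$values),
              if (!is.null(x$calls)) " (with detection calls)" else ""))
  invisible(x)
}

gene_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Construct a RankMatrix
#'
#' Genes-by-samples matrix of within-sample percentile rank scores in
#' `[0, 100]`. Usually produced by [rank_matrix()] rather than directly.
#'
#' @param values Numeric matrix of rank scores with gene/sample dimnames.
#' @param platform Platform tag carried over from the source matrix.
#' @return An object of class `RankMatrix`.
#' @export
RankMatrix <- function(values, platform) {
  platform <- match.arg(platform, PLATFORMS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene and sample identifiers are required")
  if (anyNA(values) || any(values < 0) || any(values > 100))
    stop("rank scores must lie in [0, 100]")
  structure(list(values = values, platform = platform), class = "RankMatrix")
}

#' @export
dim.RankMatrix <- function(x) dim(x$values)

#' @export
print.RankMatrix <- function(x, ...) {
  cat(sprintf("RankMatrix [%s]: %d genes x %d samples\n",
              x$platform, nrow(x$values), ncol(x$values)))
  invisible(x)
}
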