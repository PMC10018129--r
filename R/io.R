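#' Read a delimited expression table
#'
#' Reads a TSV or CSV expression table (dialect chosen by file extension,
#' `.csv` means comma, anything else tab) into an [ExpressionMatrix]. The
#' first column (or row, see `orientation`) holds identifiers.
#'
#' @param path Path to the table.
#' @param platform Platform tag, see [ExpressionMatrix()].
#' @param orientation `"genes-in-rows"` (default) or `"samples-in-rows"`.
#' @return An [ExpressionMatrix].
#' @export
read_expression_table <- function(path, platform,
                                  orientation = c("genes-in-rows",
                                                  "samples-in-rows")) {
  orientation <- match.arg(orientation)
  sep <- table_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "#")
  if (anyDuplicated(names(df)[-1L]))
    stop("duplicate sample identifiers: ",
         paste(unique(names(df)[-1L][duplicated(names(df)[-1L])]),
               collapse = ", "))
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(body),
                                       dimnames = list(NULL, names(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row '%s', column '%s'",
                 ids[bad[["row"]]], colnames(vals)[bad[["col"]]]))
  }
  rownames(vals) <- ids
  if (orientation == "samples-in-rows") vals <- t(vals)
  ExpressionMatrix(vals, platform)
}

table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Write an expression (or any named) matrix as TSV
#'
#' Genes in rows, one leading identifier column. Round-trips with
#' [read_expression_table()].
#'
#' @param path Output path (`.csv` extension switches to comma-delimited).
#' @param m An [ExpressionMatrix] or a plain numeric matrix with dimnames.
#' @param id_name Header of the identifier column.
#' @export
write_table <- function(path, m, id_name = "gene") {
  vals <- if (inherits(m, c("ExpressionMatrix", "RankMatrix"))) m$values else m
  df <- data.frame(id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = table_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a single-cell UMI matrix in MatrixMarket triple format
#'
#' @param matrix_path Path to the `.mtx` file (genes in rows).
#' @param genes_path Text file, one gene identifier per line.
#' @param barcodes_path Text file, one cell barcode per line.
#' @return An [ExpressionMatrix] with platform `sc-umi` (dense).
#' @export
read_mtx <- function(matrix_path, genes_path, barcodes_path) {
  sm <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(genes) != nrow(sm))
    stop(sprintf("gene list has %d entries for a %d-row matrix",
                 length(genes), nrow(sm)))
  if (length(barcodes) != ncol(sm))
    stop(sprintf("barcode list has %d entries for a %d-column matrix",
                 length(barcodes), ncol(sm)))
  vals <- as.matrix(sm)
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(genes, barcodes)
  ExpressionMatrix(vals, "sc-umi")
}

#' Write a single-cell UMI matrix as a MatrixMarket triple
#'
#' @param m An [ExpressionMatrix] (platform `sc-umi`).
#' @param matrix_path,genes_path,barcodes_path Output paths.
#' @export
write_mtx <- function(m, matrix_path, genes_path, barcodes_path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), matrix_path)
  writeLines(gene_ids(m), genes_path)
  writeLines(sample_ids(m), barcodes_path)
  invisible(matrix_path)
}

#' Collapse probe sets to gene level
#'
#' When a gene is interrogated by several probe sets, the probe set with the
#' largest mean value across samples represents the gene in every sample;
#' ties are broken by the lexicographically smallest probe identifier.
#' Detection calls, when present, follow the retained probe row.
#'
#' @param m [ExpressionMatrix] whose rows are probe identifiers.
#' @param probe_to_gene Named character vector or list mapping every probe
#'   identifier in `m` to a gene symbol.
#' @return An [ExpressionMatrix] with one row per gene.
#' @export
collapse_probesets <- function(m, probe_to_gene) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  probe_to_gene <- unlist(probe_to_gene)
  probes <- gene_ids(m)
  missing <- setdiff(probes, names(probe_to_gene))
  if (length(missing))
    stop("probes absent from the probe-to-gene map: ",
         paste(missing, collapse = ", "))
  gene <- unname(probe_to_gene[probes])
  means <- rowMeans(m$values)
  # order by gene, then mean descending, then probe id ascending: the first
  # row per gene is the representative under the tie rule
  o <- order(gene, -means, probes)
  keep <- o[!duplicated(gene[o])]
  vals <- m$values[keep, , drop = FALSE]
  rownames(vals) <- gene[keep]
  calls <- m$calls
  if (!is.null(calls)) {
    calls <- calls[keep, , drop = FALSE]
    rownames(calls) <- gene[keep]
  }
  ExpressionMatrix(vals, m$platform, calls = calls)
}

#' Read a marker-alias table
#'
#' Two-column TSV (`alias`, `symbol`), with or without a header line. Alias
#' keys are matched case-insensitively; every standard symbol also maps to
#' itself.
#'
#' @param path Path to the TSV.
#' @return A named character vector (class `AliasMap`): lower-cased alias ->
#'   standard symbol.
#' @export
read_alias_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 2L) stop("alias table needs two columns: alias, symbol")
  if (tolower(df[1L, 1L]) %in% c("alias", "aliases")) df <- df[-1L, ]
  alias_map(stats::setNames(df[[2L]], df[[1L]]))
}

#' Build an AliasMap from a named vector
#'
#' @param x Named character vector, names are aliases, values standard
#'   symbols.
#' @return Named character vector of class `AliasMap` with lower-cased
#'   alias keys, closed so standard symbols map to themselves.
#' @export
alias_map <- function(x) {
  key <- tolower(names(x))
  sym <- unname(x)
  # identity closure over the standard symbols
  key <- c(key, tolower(sym))
  sym <- c(sym, sym)
  first <- !duplicated(key)
  conflict <- tapply(sym, key, function(v) length(unique(v)) > 1L)
  if (any(conflict))
    stop("alias mapped to multiple symbols: ",
         paste(names(conflict)[conflict], collapse = ", "))
  structure(stats::setNames(sym[first], key[first]), class = "AliasMap")
}

#' Read gene lengths
#'
#' @param path Two-column TSV (`gene`, `length` in bp), optional header.
#' @return Named integer vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character", comment.char = "#")
  if (tolower(df[1L, 2L]) %in% c("length", "len")) df <- df[-1L, ]
  len <- as.integer(df[[2L]])
  if (anyNA(len) || any(len < 1L)) stop("gene lengths must be integers >= 1")
  stats::setNames(len, df[[1L]])
}

#' Write / read a per-gene statistics table
#'
#' TSV with columns gene, ars, q1, q3, gpl_iqr, gpl_abs, rank_min, rank_max,
#' n_samples, platform; numeric columns written with 6 decimals.
#'
#' @param path Output path.
#' @param stats A data.frame as produced by [gene_stats_table()].
#' @export
write_gene_stats <- function(path, stats) {
  num <- vapply(stats, is.numeric, logical(1L))
  out <- stats
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  out$n_samples <- as.character(stats$n_samples)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_stats
#' @export
read_gene_stats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  df$n_samples <- as.integer(df$n_samples)
  df
}
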