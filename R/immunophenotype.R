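# Expression-tag vocabulary, longest first so greedy matching prefers
# "high" over "hi" and "medium"/"mid" stay distinct.
PHENO_TAGS <- c("medium", "bright", "high", "int", "mid", "dim",
                "hi", "lo", "+", "-")

# Map every sign variant (Unicode minus, en dash, full-width plus,
# superscript renderings already flattened to plain text) to ASCII.
normalize_signs <- function(s) {
  s <- gsub("−", "-", s)
  s <- gsub("–", "-", s)
  s <- gsub("＋", "+", s)
  s
}

#' Construct an Immunophenotype
#'
#' An immunophenotype is an ordered list of phenotypic units, each a marker
#' symbol plus an expression tag (one of `+`, `-`, `hi`, `lo`, `int`,
#' `bright`, `dim`, `mid`, `medium`, `high`). Units with identical marker
#' and tag are merged; the same marker with conflicting tags is an error.
#' The canonical key (units sorted by marker then tag) makes comparison
#' independent of writing order.
#'
#' @param markers Character vector of marker symbols.
#' @param tags Character vector of expression tags, aligned with `markers`.
#' @param unmapped Markers that failed alias resolution (bookkeeping).
#' @return Object of class `Immunophenotype`.
#' @export
immunophenotype <- function(markers, tags, unmapped = character()) {
  if (length(markers) == 0L) stop("empty immunophenotype")
  if (length(markers) != length(tags)) stop("markers and tags must align")
  if (!all(tags %in% PHENO_TAGS))
    stop("unknown expression tag(s): ",
         paste(setdiff(tags, PHENO_TAGS), collapse = ", "))
  if (any(!nzchar(markers))) stop("empty marker symbol")
  key <- paste0(markers, "\r", tags)
  dupu <- duplicated(key)
  markers <- markers[!dupu]
  tags <- tags[!dupu]
  if (anyDuplicated(markers))
    stop("marker(s) with conflicting tags: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  units <- data.frame(marker = markers, tag = tags,
                      stringsAsFactors = FALSE)
  o <- order(units$marker, units$tag)
  structure(list(units = units,
                 canonical_key = paste0(units$marker[o], units$tag[o],
                                        collapse = ""),
                 unmapped = unmapped),
            class = "Immunophenotype")
}

#' @export
format.Immunophenotype <- function(x, ...) {
  paste0(x$units$marker, x$units$tag, collapse = "")
}

#' @export
print.Immunophenotype <- function(x, ...) {
  cat("Immunophenotype:", format(x), sprintf("(%d units)\n", nrow(x$units)))
  invisible(x)
}

#' Parse an immunophenotype string
#'
#' Splits a string such as `"CD4+FOXP3+CD25hi"` into phenotypic units.
#' Marker tokens are runs of letters, digits and hyphens; at each position
#' the parser takes the shortest marker that is followed by an expression
#' tag and lets the rest of the string parse (with backtracking), matching
#' tags longest-first so `"CD26high"` reads as `CD26` + `high`, not
#' `CD26` + `hi` + an unparseable remainder, and `"CD25hiCD4+"` splits
#' into two units. Unicode minus signs are accepted as `-`. An ASCII
#' hyphen inside a marker name (as in `HLA-DR`) is indistinguishable from
#' a negative tag followed by a second marker; supply `aliases` so known
#' marker names (longest first) are matched before the general rule.
#'
#' @param s The phenotype string.
#' @param aliases Optional `AliasMap`; known aliases and symbols take
#'   precedence as marker tokens during segmentation.
#' @return An [immunophenotype()] preserving written unit order.
#' @export
parse_phenotype <- function(s, aliases = NULL) {
  s <- normalize_signs(s)
  if (!nzchar(s)) stop("empty phenotype string")
  chars <- strsplit(s, "")[[1L]]
  n <- length(chars)
  is_marker_char <- grepl("[A-Za-z0-9-]", chars)
  failed <- logical(n + 1L)  # memo of positions known not to parse
  lower <- tolower(s)
  known <- if (!is.null(aliases))
    names(aliases)[order(-nchar(names(aliases)))]
  else character()

  try_unit <- function(marker_end, i) {
    marker <- substr(s, i, marker_end)
    rest <- marker_end + 1L
    for (tag in PHENO_TAGS) {
      tl <- nchar(tag)
      if (rest + tl - 1L <= n && substr(s, rest, rest + tl - 1L) == tag) {
        tail <- parse_from(rest + tl)
        if (!is.null(tail)) return(c(list(c(marker, tag)), tail))
      }
    }
    NULL
  }

  parse_from <- function(i) {
    if (i > n) return(list())
    if (failed[i]) return(NULL)
    # lexicon first: longest known marker name anchored at i
    for (k in known) {
      kl <- nchar(k)
      if (i + kl - 1L <= n && substr(lower, i, i + kl - 1L) == k) {
        res <- try_unit(i + kl - 1L, i)
        if (!is.null(res)) return(res)
      }
    }
    # general rule: shortest marker whose following tag lets the rest parse
    j <- i
    while (j <= n && is_marker_char[j]) j <- j + 1L
    run_end <- j - 1L
    if (run_end >= i) {
      for (end in i:run_end) {
        res <- try_unit(end, i)
        if (!is.null(res)) return(res)
      }
    }
    failed[i] <<- TRUE
    NULL
  }

  units <- parse_from(1L)
  if (is.null(units))
    stop("cannot parse phenotype '", s,
         "': no complete marker+tag segmentation (check for a trailing ",
         "marker without an expression tag)")
  immunophenotype(vapply(units, `[`, character(1L), 1L),
                  vapply(units, `[`, character(1L), 2L))
}

#' Normalize an immunophenotype via an alias map
#'
#' Replaces each marker by its standard gene symbol (case-insensitive
#' lookup). Unresolvable markers are kept verbatim and listed in the
#' result's `unmapped` field. After mapping, identical units are merged
#' and conflicting tags on one symbol raise an error.
#'
#' @param p An [immunophenotype()].
#' @param a An `AliasMap` from [alias_map()] / [read_alias_table()].
#' @return A normalized [immunophenotype()]. Idempotent.
#' @export
normalize_phenotype <- function(p, a) {
  stopifnot(inherits(p, "Immunophenotype"))
  key <- tolower(p$units$marker)
  hit <- key %in% names(a)
  markers <- ifelse(hit, unname(a[key]), p$units$marker)
  immunophenotype(markers, p$units$tag,
                  unmapped = p$units$marker[!hit])
}

#' Split an immunophenotype into layer-k children
#'
#' All `choose(n, k)` subsets of the phenotypic units, deduplicated by
#' canonical key (writing order is irrelevant). `k = 1` gives the units
#' themselves, `k = n` the phenotype itself.
#'
#' @param p An [immunophenotype()] with `n` units.
#' @param k Layer, `1 <= k <= n`.
#' @return List of [immunophenotype()] children.
#' @export
split_layers <- function(p, k) {
  stopifnot(inherits(p, "Immunophenotype"))
  n <- nrow(p$units)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  combos <- utils::combn(n, k, simplify = FALSE)
  children <- lapply(combos, function(idx)
    immunophenotype(p$units$marker[idx], p$units$tag[idx]))
  children[!duplicated(vapply(children, `[[`, character(1L),
                              "canonical_key"))]
}

#' Enumerate the binary expression states of a gene combination
#'
#' A combination of `n` highly plastic genes spans `2^n` immunophenotypes:
#' every assignment of `+` (high) or `-` (low/no expression) to the genes.
#'
#' @param genes Character vector of distinct gene symbols.
#' @return List of `2^n` canonical [immunophenotype()] objects.
#' @export
enumerate_states <- function(genes) {
  n <- length(genes)
  if (n < 1L) stop("at least one gene required")
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  grid <- expand.grid(rep(list(c("+", "-")), n), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    immunophenotype(genes, unlist(grid[i, ], use.names = FALSE)))
}

#' Plasticity support of an immunophenotype
#'
#' An immunophenotype is supported by gene plasticity when every member
#' gene's absolute GPL score reaches `cutoff` on either (mode `"either"`)
#' or both (mode `"both"`) platforms. Genes missing from the statistics
#' make the phenotype unsupported and are listed.
#'
#' @param p An [immunophenotype()] with standard symbols.
#' @param merged Result of [merge_platforms()] (or its `stats` element).
#' @param cutoff Absolute GPL cutoff, default 50.
#' @param mode `"either"` or `"both"`.
#' @return List: `supported` (logical), `gpl` (data.frame gene /
#'   gpl_abs_array / gpl_abs_rnaseq), `missing`.
#' @export
layer_support <- function(p, merged, cutoff = 50,
                          mode = c("either", "both")) {
  stopifnot(inherits(p, "Immunophenotype"))
  mode <- match.arg(mode)
  m <- if (is.data.frame(merged)) merged else merged$stats
  genes <- p$units$marker
  idx <- match(genes, m$gene)
  missing <- genes[is.na(idx)]
  gpl <- data.frame(gene = genes,
                    gpl_abs_array = m$gpl_abs_array[idx],
                    gpl_abs_rnaseq = m$gpl_abs_rnaseq[idx],
                    stringsAsFactors = FALSE)
  eff <- if (mode == "either")
    pmax(gpl$gpl_abs_array, gpl$gpl_abs_rnaseq)
  else
    pmin(gpl$gpl_abs_array, gpl$gpl_abs_rnaseq)
  supported <- length(missing) == 0L && all(eff >= cutoff)
  list(supported = supported, gpl = gpl, missing = missing)
}

#' Corpus-level immunophenotype statistics
#'
#' @param phenotypes List of (normalized) [immunophenotype()] objects.
#' @return List: `n_phenotypes` (nonredundant count by canonical key),
#'   `unit_histogram` (table of unit counts over nonredundant phenotypes),
#'   `markers` (nonredundant marker symbols), `n_layer2`/`n_layer3`
#'   (globally nonredundant 2- and 3-layer combination counts from
#'   [split_layers()] children).
#' @export
corpus_stats <- function(phenotypes) {
  if (length(phenotypes) == 0L)
    return(list(n_phenotypes = 0L, unit_histogram = table(integer()),
                markers = character(), n_layer2 = 0L, n_layer3 = 0L))
  keys <- vapply(phenotypes, `[[`, character(1L), "canonical_key")
  phen <- phenotypes[!duplicated(keys)]
  sizes <- vapply(phen, function(p) nrow(p$units), integer(1L))
  layer_keys <- function(k) {
    keys <- unlist(lapply(phen[sizes >= k], function(p)
      vapply(split_layers(p, k), `[[`, character(1L), "canonical_key")))
    length(unique(keys))
  }
  list(n_phenotypes = length(phen),
       unit_histogram = table(sizes),
       markers = sort(unique(unlist(lapply(phen,
                                           function(p) p$units$marker)))),
       n_layer2 = layer_keys(2L),
       n_layer3 = layer_keys(3L))
}

#' Extract candidate immunophenotype strings from plain text
#'
#' Scans text with literature-mining regular expressions of the form
#' `.{0,20}[+-].{0,12}[TB].{0,12}cell` — a sign (or graded expression
#' label such as `hi`, `lo`, `bright`, `dim`, `int`, `mid`, `medium`,
#' `high`) within a short window of a T/B-cell mention. Unicode minus is
#' accepted as a negative sign. No deduplication is performed.
#'
#' @param text A single string of plain text.
#' @param patterns Character vector of PCRE patterns; the default covers
#'   sign-tagged and label-tagged phenotypes near "cell".
#' @return data.frame with `start`, `end` (character offsets into the
#'   sign-normalized text) and `match`; zero rows when nothing matches.
#' @export
extract_candidates <- function(text, patterns = NULL) {
  if (is.null(patterns)) {
    labels <- "(?:bright|medium|high|dim|int|mid|hi|lo)"
    patterns <- c(
      ".{0,20}[+-].{0,12}[TB].{0,12}cell",
      paste0(".{0,20}", labels, ".{0,12}[TB].{0,12}cell"))
  }
  text <- normalize_signs(text)
  out <- lapply(patterns, function(pat) {
    m <- gregexpr(pat, text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L,
               match = regmatches(text, list(m))[[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}
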