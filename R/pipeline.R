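#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: output directory, master
#' seed, synthetic-data conditions, virtual-sorting filters, the TPM
#' cutoff series for coexistence, and the polarized-gene screen
#' thresholds.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Master integer seed; also used for the simulation config
#'   unless one is supplied.
#' @param sim A [synthetic_config()]; defaults to the standard conditions
#'   at this seed.
#' @param vsort A [vsort_params()].
#' @param tpm_cutoffs TPM presence cutoffs for coexistence (default
#'   1, 2, 3, 4, 5, 10, 20).
#' @param gpl_min,rankmax_min Polarized-screen thresholds (50 / 90).
#' @param gsea_nperm Permutations for the enrichment stage (default 1000).
#' @return Named list of class `RunConfig`.
#' @export
run_config <- function(outdir, seed,
                       sim = synthetic_config(seed = seed),
                       vsort = vsort_params(),
                       tpm_cutoffs = c(1, 2, 3, 4, 5, 10, 20),
                       gpl_min = 50, rankmax_min = 90,
                       gsea_nperm = 1000L) {
  if (missing(outdir) || missing(seed)) stop("'outdir' and 'seed' required")
  if (any(tpm_cutoffs <= 0)) stop("TPM cutoffs must be positive")
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 vsort = vsort, tpm_cutoffs = tpm_cutoffs,
                 gpl_min = gpl_min, rankmax_min = rankmax_min,
                 gsea_nperm = as.integer(gsea_nperm)),
            class = "RunConfig")
}

config_hash <- function(rc) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(rc)[setdiff(names(rc), "outdir")], tmp)
  unname(tools::md5sum(tmp))
}

pipeline_header <- function(rc, hash) {
  sprintf("# plasticitome %s; seed=%d; config=%s",
          as.character(utils::packageVersion("plasticitome")),
          rc$seed, hash)
}

write_stage_tsv <- function(path, df, header) {
  writeLines(header, path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order — simulate, rank, plasticity,
#' screen, vsort, coexist, phen, gsea — writing every stage output as TSV
#' (or MTX triple) under the configured output directory, each TSV carrying
#' a header comment with the tool version, config hash and seed. A JSON
#' run manifest lists the outputs of all stages. Stage failures propagate
#' with the stage name; outputs of completed stages are left intact.
#'
#' @param rc A [run_config()].
#' @return The manifest (list), invisibly written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "RunConfig"))
  dir.create(rc$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(rc)
  hdr <- pipeline_header(rc, hash)
  out <- function(...) file.path(rc$outdir, ...)
  manifest <- list(tool = "plasticitome",
                   version = as.character(
                     utils::packageVersion("plasticitome")),
                   seed = rc$seed, config_hash = hash, stages = list())
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- res
    res
  }

  env <- new.env()
  stage("simulate", function() {
    env$bulk <- generate_bulk(rc$sim)
    env$sc <- generate_singlecell(rc$sim, env$bulk$truth)
    env$corpus <- generate_marker_corpus(seed = rc$sim$seed)
    write_stage_tsv(out("array_signal.tsv"),
                    cbind(gene = rownames(env$bulk$array$values),
                          as.data.frame(env$bulk$array$values)), hdr)
    write_stage_tsv(out("array_calls.tsv"),
                    cbind(gene = rownames(env$bulk$array$calls),
                          as.data.frame(env$bulk$array$calls)), hdr)
    write_stage_tsv(out("rnaseq_counts.tsv"),
                    cbind(gene = rownames(env$bulk$rnaseq$values),
                          as.data.frame(env$bulk$rnaseq$values)), hdr)
    write_stage_tsv(out("lengths.tsv"),
                    data.frame(gene = names(env$bulk$lengths),
                               length = env$bulk$lengths), hdr)
    write_mtx(env$sc$sc, out("sc.mtx"), out("sc_genes.txt"),
              out("sc_barcodes.txt"))
    write_stage_tsv(out("truth_states.tsv"),
                    cbind(driver = rownames(env$bulk$truth$states),
                          as.data.frame(env$bulk$truth$states)), hdr)
    write_stage_tsv(out("truth_gene_class.tsv"),
                    data.frame(gene = names(env$bulk$truth$gene_class),
                               class = unname(env$bulk$truth$gene_class)),
                    hdr)
    writeLines(env$corpus$phenotypes, out("corpus.txt"))
    list(outputs = c("array_signal.tsv", "array_calls.tsv",
                     "rnaseq_counts.tsv", "lengths.tsv", "sc.mtx",
                     "sc_genes.txt", "sc_barcodes.txt",
                     "truth_states.tsv", "truth_gene_class.tsv",
                     "corpus.txt"))
  })

  stage("rank", function() {
    env$ranks_array <- rank_matrix(env$bulk$array)
    env$ranks_rnaseq <- rank_matrix(env$bulk$rnaseq, env$bulk$lengths)
    write_stage_tsv(out("ranks_array.tsv"),
                    cbind(gene = rownames(env$ranks_array$values),
                          as.data.frame(env$ranks_array$values)), hdr)
    write_stage_tsv(out("ranks_rnaseq.tsv"),
                    cbind(gene = rownames(env$ranks_rnaseq$values),
                          as.data.frame(env$ranks_rnaseq$values)), hdr)
    list(outputs = c("ranks_array.tsv", "ranks_rnaseq.tsv"))
  })

  stage("plasticity", function() {
    env$stats_array <- gene_stats_table(env$ranks_array)
    env$stats_rnaseq <- gene_stats_table(env$ranks_rnaseq)
    env$merged <- merge_platforms(env$stats_array, env$stats_rnaseq)
    write_gene_stats(out("gene_stats_array.tsv"), env$stats_array)
    write_gene_stats(out("gene_stats_rnaseq.tsv"), env$stats_rnaseq)
    write_stage_tsv(out("merged_stats.tsv"), env$merged$stats, hdr)
    list(outputs = c("gene_stats_array.tsv", "gene_stats_rnaseq.tsv",
                     "merged_stats.tsv"),
         ars_pearson = env$merged$ars_pearson)
  })

  stage("screen", function() {
    env$polarized <- screen_polarized(env$merged, rc$gpl_min,
                                      rc$rankmax_min)
    writeLines(env$polarized, out("polarized.txt"))
    list(outputs = "polarized.txt", n_polarized = length(env$polarized))
  })

  stage("vsort", function() {
    drivers <- intersect(env$bulk$truth$drivers, env$polarized)
    if (length(drivers) == 0L) drivers <- env$bulk$truth$drivers[1L]
    env$vsorts <- lapply(drivers, function(d)
      virtual_sort(d, env$ranks_rnaseq, rc$vsort))
    names(env$vsorts) <- drivers
    files <- vapply(drivers, function(d) {
      f <- paste0("vsort_", d, ".tsv")
      write_stage_tsv(out(f), env$vsorts[[d]]$table, hdr)
      f
    }, character(1L))
    list(outputs = unname(files))
  })

  stage("coexist", function() {
    v <- env$vsorts[[1L]]
    tpm <- apply(env$bulk$rnaseq$values, 2L, function(x)
      tpm_from_counts(stats::setNames(x, rownames(env$bulk$rnaseq$values)),
                      env$bulk$lengths))
    rownames(tpm) <- rownames(env$bulk$rnaseq$values)
    partners <- c(utils::head(v$correlated, 5L),
                  utils::head(v$anticorrelated, 5L))
    rows <- do.call(rbind, lapply(partners, function(g)
      do.call(rbind, lapply(rc$tpm_cutoffs, function(ct) {
        cx <- coexist_tpm(tpm[v$target, ], tpm[g, ], ct)
        data.frame(target = v$target, partner = g, cutoff = ct,
                   coexistence = cx$coexistence_rate, apa = cx$apa_rate)
      }))))
    write_stage_tsv(out("coexist.tsv"), rows, hdr)
    sc_eval <- evaluate_vsort_sc(v, env$sc$sc)
    write_stage_tsv(out("sc_eval.tsv"), sc_eval$per_gene, hdr)
    list(outputs = c("coexist.tsv", "sc_eval.tsv"),
         sc_summary = sc_eval$summary[c("pearson_direction_supported",
                                        "pp_direction_supported")])
  })

  stage("phen", function() {
    parsed <- lapply(env$corpus$phenotypes, parse_phenotype)
    normed <- lapply(parsed, normalize_phenotype, a = env$corpus$aliases)
    cs <- corpus_stats(normed)
    mpf <- marker_plastic_fraction(env$corpus$truth$marker,
                                   env$corpus$merged_stats)
    write_stage_tsv(out("phen_summary.tsv"),
                    data.frame(metric = c("n_phenotypes", "n_markers",
                                          "n_layer2", "n_layer3",
                                          "marker_plastic_percent"),
                               value = c(cs$n_phenotypes,
                                         length(cs$markers),
                                         cs$n_layer2, cs$n_layer3,
                                         mpf$percent)), hdr)
    list(outputs = "phen_summary.tsv",
         marker_plastic_percent = mpf$percent)
  })

  stage("gsea", function() {
    rl <- ranked_list(env$merged$stats$gene,
                      env$merged$stats$gpl_abs_rnaseq)
    planted <- names(env$bulk$truth$gene_class)[
      env$bulk$truth$gene_class %in% c("driver", "correlated",
                                       "anticorrelated")]
    er <- nes_pvalue(rl, intersect(planted, rl$genes),
                     n_perm = rc$gsea_nperm, seed = rc$seed)
    write_stage_tsv(out("enrichment.tsv"),
                    data.frame(es = er$es, nes = er$nes,
                               p_value = er$p_value,
                               n_permutations = er$n_permutations), hdr)
    list(outputs = "enrichment.tsv", es = er$es, p_value = er$p_value)
  })

  jsonlite::write_json(manifest, file.path(rc$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
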