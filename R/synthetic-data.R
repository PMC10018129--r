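#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by [generate_bulk()] and
#' [generate_singlecell()]: multi-condition bulk profiles in which lowly
#' plastic housekeeping and silent genes coexist with highly plastic
#' driver genes whose on/off state across samples carries blocks of
#' correlated and anticorrelated genes, plus single-cell UMI data with
#' dropout mirroring the same structure.
#'
#' Expression means are on a TPM-like linear scale. Driver and block genes
#' sit at `block_off_mean` when off and `block_off_mean * effect_size`
#' when on; the defaults (0.05 and 20000, i.e. an on state of 1000) mirror
#' marker genes that swing between silence (well below 1 TPM, usually
#' undetected) and strong expression (around a thousand TPM) — the
#' bipolar behaviour that makes a gene a useful sorting marker.
#' Housekeeping genes are constitutively expressed with gene-specific
#' means in a log-normal band around `hk_mean`, silent genes sit near
#' zero, and `noise` background genes have stable gene-specific means
#' spanning the dynamic range.
#'
#' @param n_samples Bulk samples per platform (default 60).
#' @param n_cells Single cells (default 300).
#' @param seed Mandatory integer seed.
#' @param housekeeping_high,silent,drivers,correlated_per_driver,anticorrelated_per_driver,noise
#'   Gene-class sizes (defaults 100/100/5/20/20/100).
#' @param driver_on_fraction Probability a driver is in its on state in a
#'   sample or cell (default 0.5).
#' @param effect_size Fold separation between on and off states
#'   (default 20000).
#' @param noise_sd Log-normal measurement noise sd on the natural-log
#'   scale (default 0.25).
#' @param nb_dispersion Negative-binomial dispersion for counts; variance
#'   is `mu + dispersion * mu^2` (default 0.05, sorted-population bulk
#'   scale).
#' @param dropout_rate Independent Bernoulli thinning probability applied
#'   to single-cell entries (default 0.3).
#' @param block_off_mean Off-state mean for driver/block genes
#'   (default 0.05).
#' @param hk_mean,silent_mean Means for housekeeping and silent genes
#'   (defaults 500 and 0.02).
#' @param array_noise_floor Signal above which an array detection call is
#'   "P" (default 1).
#' @return Named list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_samples = 60L, n_cells = 300L, seed,
                             housekeeping_high = 100L, silent = 100L,
                             drivers = 5L, correlated_per_driver = 20L,
                             anticorrelated_per_driver = 20L, noise = 100L,
                             driver_on_fraction = 0.5, effect_size = 20000,
                             noise_sd = 0.25, nb_dispersion = 0.05,
                             dropout_rate = 0.3, block_off_mean = 0.05,
                             hk_mean = 500, silent_mean = 0.02,
                             array_noise_floor = 1) {
  if (missing(seed)) stop("'seed' is mandatory")
  sizes <- c(n_samples, n_cells, housekeeping_high, silent, drivers,
             correlated_per_driver, anticorrelated_per_driver, noise)
  if (any(sizes < 0)) stop("sizes must be non-negative")
  if (n_samples < 2L) stop("at least two samples required")
  if (drivers < 1L) stop("at least one driver required")
  if (driver_on_fraction <= 0 || driver_on_fraction > 1)
    stop("driver_on_fraction must lie in (0, 1]")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must lie in [0, 1]")
  if (effect_size <= 1) stop("effect_size must exceed 1")
  if (noise_sd < 0 || nb_dispersion < 0)
    stop("noise_sd and nb_dispersion must be non-negative")
  structure(list(n_samples = as.integer(n_samples),
                 n_cells = as.integer(n_cells), seed = as.integer(seed),
                 housekeeping_high = as.integer(housekeeping_high),
                 silent = as.integer(silent), drivers = as.integer(drivers),
                 correlated_per_driver = as.integer(correlated_per_driver),
                 anticorrelated_per_driver =
                   as.integer(anticorrelated_per_driver),
                 noise = as.integer(noise),
                 driver_on_fraction = driver_on_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 nb_dispersion = nb_dispersion,
                 dropout_rate = dropout_rate,
                 block_off_mean = block_off_mean, hk_mean = hk_mean,
                 silent_mean = silent_mean,
                 array_noise_floor = array_noise_floor),
            class = "SyntheticConfig")
}

# Gene universe and latent mean model shared by bulk and single-cell
# generation. Returns per-gene class labels, driver memberships and the
# deterministic mean-given-state function.
synthetic_universe <- function(cfg) {
  pad <- function(prefix, n) if (n > 0L)
    sprintf("%s%03d", prefix, seq_len(n)) else character()
  hk <- pad("HK", cfg$housekeeping_high)
  sil <- pad("SIL", cfg$silent)
  drv <- pad("DRV", cfg$drivers)
  noise <- pad("BG", cfg$noise)
  corr <- list()
  anti <- list()
  for (d in seq_len(cfg$drivers)) {
    corr[[drv[d]]] <- if (cfg$correlated_per_driver > 0L)
      sprintf("COR%d_%03d", d, seq_len(cfg$correlated_per_driver))
    else character()
    anti[[drv[d]]] <- if (cfg$anticorrelated_per_driver > 0L)
      sprintf("ANT%d_%03d", d, seq_len(cfg$anticorrelated_per_driver))
    else character()
  }
  genes <- c(hk, sil, drv, unlist(corr, use.names = FALSE),
             unlist(anti, use.names = FALSE), noise)
  class <- c(rep("housekeeping", length(hk)),
             rep("silent", length(sil)),
             rep("driver", length(drv)),
             rep("correlated", sum(lengths(corr))),
             rep("anticorrelated", sum(lengths(anti))),
             rep("noise", length(noise)))
  names(class) <- genes
  list(genes = genes, class = class, drivers = drv,
       correlated = corr, anticorrelated = anti,
       housekeeping = hk, silent = sil, noise = noise)
}

# Stable per-gene baseline means for the state-independent classes, drawn
# once per dataset so bulk and single-cell data share them. Housekeeping
# genes get gene-specific means around hk_mean (a log-normal band, so
# genes do not all tie at one value), background genes span the dynamic
# range log-uniformly.
draw_base_means <- function(cfg, uni) {
  means <- numeric(0)
  if (length(uni$housekeeping))
    means <- c(means, stats::setNames(
      stats::rlnorm(length(uni$housekeeping),
                    meanlog = log(cfg$hk_mean), sdlog = 0.5),
      uni$housekeeping))
  if (length(uni$silent))
    means <- c(means, stats::setNames(
      rep(cfg$silent_mean, length(uni$silent)), uni$silent))
  if (length(uni$noise))
    means <- c(means, stats::setNames(
      exp(stats::runif(length(uni$noise), log(0.5), log(800))),
      uni$noise))
  means
}

# Per-gene mean matrix (genes x conditions) given the binary driver-state
# matrix (drivers x conditions) and the fixed baseline means.
synthetic_means <- function(cfg, uni, states, base_means) {
  n_cond <- ncol(states)
  on_mean <- cfg$block_off_mean * cfg$effect_size
  mu <- matrix(0, nrow = length(uni$genes), ncol = n_cond,
               dimnames = list(uni$genes, colnames(states)))
  fixed <- names(base_means)
  if (length(fixed)) mu[fixed, ] <- base_means
  for (d in uni$drivers) {
    on <- states[d, ] == 1L
    mu[d, ] <- ifelse(on, on_mean, cfg$block_off_mean)
    if (length(uni$correlated[[d]]))
      mu[uni$correlated[[d]], ] <-
        matrix(ifelse(on, on_mean, cfg$block_off_mean),
               nrow = length(uni$correlated[[d]]),
               ncol = n_cond, byrow = TRUE)
    if (length(uni$anticorrelated[[d]]))
      mu[uni$anticorrelated[[d]], ] <-
        matrix(ifelse(on, cfg$block_off_mean, on_mean),
               nrow = length(uni$anticorrelated[[d]]),
               ncol = n_cond, byrow = TRUE)
  }
  mu
}

draw_states <- function(cfg, n_cond, cond_ids, drivers) {
  states <- matrix(stats::rbinom(length(drivers) * n_cond, 1L,
                                 cfg$driver_on_fraction),
                   nrow = length(drivers),
                   dimnames = list(drivers, cond_ids))
  # every driver should toggle at least once (otherwise it is not
  # plastic); an always-on fraction of exactly 1 is honoured as requested
  if (cfg$driver_on_fraction < 1) {
    for (d in seq_len(nrow(states))) {
      if (all(states[d, ] == states[d, 1L]))
        states[d, 1L] <- 1L - states[d, 1L]
    }
  }
  states
}

#' Generate matched bulk array and RNA-Seq datasets with planted truth
#'
#' One latent truth drives both platforms: each driver's on/off state is
#' drawn per sample, correlated members are high exactly when their driver
#' is on, anticorrelated members exactly when it is off, housekeeping
#' genes are high everywhere and silent genes low everywhere. Array
#' signals are log-normal around the mean with present calls above the
#' noise floor; RNA-Seq counts are negative-binomial with matched means
#' scaled by gene length.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `array` (ExpressionMatrix `array-signal` with calls),
#'   `rnaseq` (ExpressionMatrix `rnaseq-count`), `lengths` (named gene
#'   lengths in bp), and `truth` (list: `gene_class`, `drivers`,
#'   `correlated`, `anticorrelated`, `states` drivers-by-samples).
#' @export
generate_bulk <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  uni <- synthetic_universe(cfg)
  with_local_seed(cfg$seed, {
    n <- cfg$n_samples
    samples <- sprintf("S%03d", seq_len(n))
    states <- draw_states(cfg, n, samples, uni$drivers)
    base_means <- draw_base_means(cfg, uni)
    mu <- synthetic_means(cfg, uni, states, base_means)
    ng <- nrow(mu)

    signal <- mu * exp(matrix(stats::rnorm(ng * n, sd = cfg$noise_sd),
                              ng, n))
    calls <- matrix(ifelse(signal > cfg$array_noise_floor, "P", "A"), ng, n,
                    dimnames = dimnames(mu))
    array_m <- ExpressionMatrix(signal, "array-signal", calls = calls)

    lengths <- stats::setNames(
      as.integer(round(stats::runif(ng, 500, 5000))), uni$genes)
    mu_counts <- mu * exp(matrix(stats::rnorm(ng * n, sd = cfg$noise_sd),
                                 ng, n)) * lengths / 1000
    counts <- matrix(
      stats::rnbinom(ng * n, mu = mu_counts,
                     size = if (cfg$nb_dispersion > 0)
                       1 / cfg$nb_dispersion else Inf),
      ng, n, dimnames = dimnames(mu))
    storage.mode(counts) <- "double"
    rnaseq_m <- ExpressionMatrix(counts, "rnaseq-count")

    list(array = array_m, rnaseq = rnaseq_m, lengths = lengths,
         truth = list(gene_class = uni$class, drivers = uni$drivers,
                      correlated = uni$correlated,
                      anticorrelated = uni$anticorrelated,
                      states = states,
                      base_means = base_means))
  })
}

#' Generate a single-cell UMI matrix from the same planted truth
#'
#' Cells inherit the driver-state model of the bulk truth: each cell draws
#' its own on/off state per driver, the cell's expected expression profile
#' follows the bulk mean model scaled to a target library size, UMI counts
#' are negative-binomial, and dropout is independent Bernoulli thinning of
#' entries — reproducing the characteristic excess of zeros in single-cell
#' data.
#'
#' @param cfg A [synthetic_config()].
#' @param truth Truth list from [generate_bulk()] (provides the gene
#'   universe and background means so bulk and single-cell data share one
#'   structure).
#' @param target_umis Expected UMI total per cell before dropout
#'   (default 5000).
#' @return List with `sc` (ExpressionMatrix `sc-umi`) and `cell_states`
#'   (drivers-by-cells binary matrix).
#' @export
generate_singlecell <- function(cfg, truth, target_umis = 5000) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  uni <- synthetic_universe(cfg)
  with_local_seed(cfg$seed + 1L, {
    nc <- cfg$n_cells
    cells <- sprintf("C%04d", seq_len(nc))
    cell_states <- draw_states(cfg, nc, cells, uni$drivers)
    mu <- synthetic_means(cfg, uni, cell_states, truth$base_means)
    mu <- sweep(mu, 2L, colSums(mu), "/") * target_umis
    ng <- nrow(mu)
    counts <- matrix(
      stats::rnbinom(ng * nc, mu = mu,
                     size = if (cfg$nb_dispersion > 0)
                       1 / cfg$nb_dispersion else Inf),
      ng, nc, dimnames = dimnames(mu))
    if (cfg$dropout_rate > 0) {
      keep <- matrix(stats::rbinom(ng * nc, 1L, 1 - cfg$dropout_rate),
                     ng, nc)
      counts <- counts * keep
    }
    storage.mode(counts) <- "double"
    list(sc = ExpressionMatrix(counts, "sc-umi"),
         cell_states = cell_states)
  })
}

#' Generate a synthetic immunophenotype corpus with planted plasticity
#'
#' Emits phenotype strings over a planted marker universe with a
#' controlled unit-count distribution and optional alias spellings, plus a
#' truth table recording which markers are planted as highly plastic and a
#' merged-statistics table consistent with that truth (plastic markers at
#' `gpl_abs` 50 or above on both platforms, the rest below on both).
#'
#' @param n_markers Size of the marker universe (default 171).
#' @param n_plastic Number planted as highly plastic (default 159).
#' @param n_phenotypes Number of corpus strings (default 400).
#' @param unit_probs Probabilities of a phenotype having 1, 2, 3, 4, 5
#'   units; the default puts ~83% of phenotypes at three or fewer genes.
#' @param alias_fraction Fraction of marker mentions written as an alias
#'   (default 0.25).
#' @param seed Integer seed.
#' @return List with `phenotypes` (character vector), `aliases`
#'   (AliasMap), `truth` (data.frame marker / plastic), and `merged_stats`
#'   (data.frame usable by [marker_plastic_fraction()] and
#'   [layer_support()]).
#' @export
generate_marker_corpus <- function(n_markers = 171L, n_plastic = 159L,
                                   n_phenotypes = 400L,
                                   unit_probs = c(0.35, 0.30, 0.18,
                                                  0.10, 0.07),
                                   alias_fraction = 0.25, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (n_plastic > n_markers) stop("n_plastic cannot exceed n_markers")
  with_local_seed(seed, {
    markers <- sprintf("MK%03d", seq_len(n_markers))
    plastic <- c(rep(TRUE, n_plastic), rep(FALSE, n_markers - n_plastic))
    aliases <- stats::setNames(markers, sprintf("CDX%03d", seq_len(n_markers)))
    tags <- c("+", "-", "hi", "lo")
    tag_probs <- c(0.55, 0.25, 0.12, 0.08)
    sizes <- sample(seq_along(unit_probs), n_phenotypes, replace = TRUE,
                    prob = unit_probs)
    phen <- vapply(sizes, function(k) {
      mk <- sample(markers, k)
      written <- ifelse(stats::runif(k) < alias_fraction,
                        names(aliases)[match(mk, aliases)], mk)
      tg <- sample(tags, k, replace = TRUE, prob = tag_probs)
      paste0(written, tg, collapse = "")
    }, character(1L))
    # merged stats consistent with the planted truth, on both platforms
    gpl_hi <- stats::runif(n_markers, 55, 100)
    gpl_lo <- stats::runif(n_markers, 0, 45)
    gpl_a <- ifelse(plastic, gpl_hi, gpl_lo)
    gpl_r <- ifelse(plastic, stats::runif(n_markers, 55, 100), gpl_lo)
    merged <- data.frame(gene = markers,
                         gpl_abs_array = gpl_a,
                         gpl_abs_rnaseq = gpl_r,
                         rank_max_array = stats::runif(n_markers, 80, 100),
                         rank_max_rnaseq = stats::runif(n_markers, 80, 100),
                         ars_array = stats::runif(n_markers, 20, 90),
                         ars_rnaseq = stats::runif(n_markers, 20, 90),
                         stringsAsFactors = FALSE)
    list(phenotypes = phen,
         aliases = alias_map(aliases),
         truth = data.frame(marker = markers, plastic = plastic,
                            stringsAsFactors = FALSE),
         merged_stats = merged)
  })
}
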