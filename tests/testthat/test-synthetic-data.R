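test_that("generation is deterministic given config and seed", {
  cfg <- small_config(seed = 111L)
  a <- generate_bulk(cfg)
  b <- generate_bulk(cfg)
  expect_identical(a$array$values, b$array$values)
  expect_identical(a$rnaseq$values, b$rnaseq$values)
  expect_identical(a$lengths, b$lengths)
  expect_identical(a$truth$states, b$truth$states)
  sc1 <- generate_singlecell(cfg, a$truth)
  sc2 <- generate_singlecell(cfg, b$truth)
  expect_identical(sc1$sc$values, sc2$sc$values)

  other <- generate_bulk(small_config(seed = 112L))
  expect_false(identical(a$rnaseq$values, other$rnaseq$values))
})

test_that("the generator validates its configuration before sampling", {
  expect_error(synthetic_config(seed = 1L, driver_on_fraction = 0),
               "driver_on_fraction")
  expect_error(synthetic_config(seed = 1L, effect_size = 0.5),
               "effect_size")
  expect_error(synthetic_config(seed = 1L, dropout_rate = 1.5),
               "dropout_rate")
  expect_error(synthetic_config(n_samples = 1L, seed = 1L), "two samples")
  expect_error(synthetic_config(1, 2), "seed")
})

test_that("planted gene classes separate as designed in low-noise conditions", {
  cfg <- small_config(seed = 113L, noise_sd = 0, nb_dispersion = 0)
  b <- generate_bulk(cfg)
  sr <- gene_stats_table(rank_matrix(b$rnaseq, b$lengths))
  sa <- gene_stats_table(rank_matrix(b$array))
  cls <- b$truth$gene_class
  drv <- names(cls)[cls == "driver"]
  hk <- names(cls)[cls == "housekeeping"]
  # drivers hit rank 0 when silent, near 100 when on: absolute GPL >= 90
  expect_gte(min(sr$gpl_abs[match(drv, sr$gene)]), 90)
  expect_gte(min(sa$gpl_abs[match(drv, sa$gene)]), 50)
  # housekeeping stays lowly plastic, far below every driver
  expect_lte(max(sa$gpl_abs[match(hk, sa$gene)]), 10)
  expect_lt(max(sr$gpl_abs[match(hk, sr$gene)]),
            min(sr$gpl_abs[match(drv, sr$gene)]))
})

test_that("drivers outscore housekeeping genes under default noise", {
  for (seed in c(114L, 115L, 116L)) {
    b <- generate_bulk(small_config(seed = seed))
    sr <- gene_stats_table(rank_matrix(b$rnaseq, b$lengths))
    cls <- b$truth$gene_class
    drv_min <- min(sr$gpl_abs[match(names(cls)[cls == "driver"], sr$gene)])
    hk_max <- max(sr$gpl_abs[match(names(cls)[cls == "housekeeping"],
                                   sr$gene)])
    expect_gt(drv_min, hk_max)
  }
})

test_that("an always-on driver fraction removes driver state plasticity", {
  cfg_on <- small_config(seed = 117L, driver_on_fraction = 1)
  b_on <- generate_bulk(cfg_on)
  expect_true(all(b_on$truth$states == 1L))
  sr_on <- gene_stats_table(rank_matrix(b_on$rnaseq, b_on$lengths))

  b_tog <- generate_bulk(small_config(seed = 117L))
  sr_tog <- gene_stats_table(rank_matrix(b_tog$rnaseq, b_tog$lengths))

  drv <- b_on$truth$drivers
  # residual plasticity from measurement noise only: far below the
  # state-driven plasticity of toggling drivers
  expect_lt(max(sr_on$gpl_abs[match(drv, sr_on$gene)]),
            min(sr_tog$gpl_abs[match(drv, sr_tog$gene)]) - 30)
})

test_that("detection calls flag signals above the array noise floor", {
  cfg <- small_config(seed = 118L)
  b <- generate_bulk(cfg)
  expect_identical(b$array$calls,
                   matrix(ifelse(b$array$values > cfg$array_noise_floor,
                                 "P", "A"),
                          nrow(b$array$values), ncol(b$array$values),
                          dimnames = dimnames(b$array$values)))
  # silent genes are called absent essentially everywhere
  sil <- names(b$truth$gene_class)[b$truth$gene_class == "silent"]
  expect_true(all(b$array$calls[sil, ] == "A"))
})

test_that("single-cell output mirrors bulk structure with dropout", {
  cfg <- small_config(seed = 119L)
  b <- generate_bulk(cfg)
  sc <- generate_singlecell(cfg, b$truth)
  expect_identical(sc$sc$platform, "sc-umi")
  expect_identical(dim(sc$sc$values),
                   c(length(b$truth$gene_class), cfg$n_cells))
  # correlated members coexist with their driver far more than
  # anticorrelated members
  d <- "DRV001"
  pp_c <- vapply(b$truth$correlated[[d]], function(g)
    sc_pp_rate(sc$sc$values[g, ], sc$sc$values[d, ]), numeric(1L))
  pp_a <- vapply(b$truth$anticorrelated[[d]], function(g)
    sc_pp_rate(sc$sc$values[g, ], sc$sc$values[d, ]), numeric(1L))
  expect_gt(stats::median(pp_c), stats::median(pp_a))

  # complete dropout silences the matrix
  wiped <- generate_singlecell(small_config(seed = 119L, dropout_rate = 1),
                               b$truth)
  expect_true(all(wiped$sc$values == 0))
})

test_that("without dropout single-cell correlations approach bulk values", {
  cfg <- small_config(seed = 120L, dropout_rate = 0, n_cells = 400L)
  b <- generate_bulk(cfg)
  r <- rank_matrix(b$rnaseq, b$lengths)
  v <- virtual_sort("DRV001", r)
  sc <- generate_singlecell(cfg, b$truth, target_umis = 20000)
  tc <- b$truth$correlated[["DRV001"]]
  sc_cor <- vapply(tc, function(g)
    stats::cor(sc$sc$values[g, ], sc$sc$values["DRV001", ]), numeric(1L))
  bulk_cor <- v$table$pearson[match(tc, v$table$gene)]
  expect_gt(min(sc_cor), 0.5)
  expect_lt(mean(abs(sc_cor - bulk_cor)), 0.3)
})

test_that("marker corpora encode the planted plastic fraction and aliases", {
  corpus <- generate_marker_corpus(seed = 121L)
  expect_identical(nrow(corpus$truth), 171L)
  expect_identical(sum(corpus$truth$plastic), 159L)
  res <- marker_plastic_fraction(corpus$truth$marker, corpus$merged_stats)
  expect_equal(res$percent, 92.98, tolerance = 0.005)

  again <- generate_marker_corpus(seed = 121L)
  expect_identical(corpus$phenotypes, again$phenotypes)
})
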