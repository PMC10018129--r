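test_that("ARS and GPL scores reproduce hand-computed values", {
  expect_equal(ars(c(50, 100)), 75)
  expect_equal(ars(rep(40, 7)), 40)
  expect_equal(ars(c(0, 25, 50, 75, 100)), 50)
  expect_error(ars(numeric()), "empty")

  expect_equal(gpl_iqr(rep(33, 6)), 0)
  # type-7 quartiles of (0, 0, 100, 100): Q1 = 0, Q3 = 100
  expect_equal(gpl_iqr(c(0, 0, 100, 100)),
               unname(diff(stats::quantile(c(0, 0, 100, 100),
                                           c(0.25, 0.75)))))
  expect_equal(gpl_iqr(c(0, 0, 100, 100)), 100)
  expect_error(gpl_iqr(5), "two samples")

  expect_equal(gpl_abs(c(10, 90)), 80)
  expect_equal(gpl_abs(rep(12, 4)), 0)
  expect_equal(gpl_abs(c(40, 0, 100, 60)), 100)
})

test_that("gene statistics tables match per-gene recomputation", {
  v <- matrix(c(10, 40, 90, 20, 0, 0, 80, 100), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  r <- toy_rank_matrix(v)
  tab <- gene_stats_table(r)
  expect_identical(tab$gene, c("gA", "gB"))
  expect_equal(tab$ars, c(mean(v[1, ]), mean(v[2, ])))
  expect_equal(tab$gpl_iqr, c(gpl_iqr(v[1, ]), gpl_iqr(v[2, ])))
  expect_equal(tab$gpl_abs, c(80, 100))
  expect_equal(tab$rank_min, c(10, 0))
  expect_equal(tab$rank_max, c(90, 100))

  # single sample: both GPL scores zero
  one <- gene_stats_table(toy_rank_matrix(v[, 1, drop = FALSE]))
  expect_equal(one$gpl_abs, c(0, 0))
  expect_equal(one$gpl_iqr, c(0, 0))

  # row permutation permutes the output rows identically
  perm <- gene_stats_table(toy_rank_matrix(v[2:1, ]))
  expect_identical(perm$gene, c("gB", "gA"))
  expect_equal(perm$ars, tab$ars[2:1])
})

test_that("GPL score ordering 0 <= iqr <= abs <= 100 holds on random matrices", {
  set.seed(21)
  for (i in 1:20) {
    r <- random_rank_matrix(30, sample(2:12, 1))
    tab <- gene_stats_table(r)
    expect_true(all(tab$gpl_iqr >= 0))
    expect_true(all(tab$gpl_iqr <= tab$gpl_abs + 1e-12))
    expect_true(all(tab$gpl_abs <= 100))
    expect_true(all(tab$rank_min <= tab$ars & tab$ars <= tab$rank_max))
  }
})

test_that("absolute GPL is monotone under sample addition and fixed under duplication", {
  set.seed(22)
  for (i in 1:15) {
    x <- stats::runif(8, 0, 100)
    extra <- stats::runif(3, 0, 100)
    expect_gte(gpl_abs(c(x, extra)), gpl_abs(x))
    expect_equal(gpl_abs(c(x, x[4])), gpl_abs(x))
    expect_equal(gpl_abs(sample(x)), gpl_abs(x))
  }
})

test_that("platform merging joins on shared genes and reports ARS correlation", {
  r <- random_rank_matrix(25, 6, platform = "array-signal")
  a <- gene_stats_table(r)
  b <- gene_stats_table(RankMatrix(r$values, "rnaseq-tpm"))
  m <- merge_platforms(a, b)
  expect_equal(m$ars_pearson, 1)
  expect_identical(nrow(m$stats), 25L)

  b_disjoint <- b
  b_disjoint$gene <- paste0("other_", b$gene)
  expect_error(merge_platforms(a, b_disjoint), "no genes shared")
})

test_that("noisy matched platforms correlate strongly but imperfectly in ARS", {
  cfg <- small_config(seed = 31L)
  b <- generate_bulk(cfg)
  m <- merge_platforms(gene_stats_table(rank_matrix(b$array)),
                       gene_stats_table(rank_matrix(b$rnaseq, b$lengths)))
  expect_gt(m$ars_pearson, 0.8)
  expect_lt(m$ars_pearson, 1)
})

test_that("the polarized screen applies both-platform thresholds", {
  stats <- data.frame(
    gene = c("sel", "low_rank", "low_gpl", "edge"),
    gpl_abs_array = c(60, 60, 40, 50),
    gpl_abs_rnaseq = c(55, 55, 60, 50),
    rank_max_array = c(95, 95, 95, 90),
    rank_max_rnaseq = c(92, 80, 92, 90))
  expect_identical(screen_polarized(stats), c("sel", "edge"))
  expect_setequal(screen_polarized(stats, 0, 0), stats$gene)
})

test_that("marker plastic fractions report n/N with missing markers excluded", {
  corpus <- generate_marker_corpus(seed = 41L)
  res <- marker_plastic_fraction(corpus$truth$marker, corpus$merged_stats)
  expect_equal(res$n, sum(corpus$truth$plastic))
  expect_equal(res$total, nrow(corpus$truth))
  expect_equal(res$percent, 159 / 171 * 100, tolerance = 1e-10)

  # cutoff 0 catches everything measured
  expect_equal(marker_plastic_fraction(corpus$truth$marker,
                                       corpus$merged_stats, 0)$fraction, 1)

  # mode "both" can never exceed mode "either"
  for (cut in c(30, 50, 70)) {
    both <- marker_plastic_fraction(corpus$truth$marker,
                                    corpus$merged_stats, cut, "both")
    either <- marker_plastic_fraction(corpus$truth$marker,
                                      corpus$merged_stats, cut, "either")
    expect_lte(both$fraction, either$fraction)
  }

  # unmeasured markers are excluded and listed, not fatal
  res <- marker_plastic_fraction(c("NOT_MEASURED", corpus$truth$marker[1:5]),
                                 corpus$merged_stats)
  expect_identical(res$missing, "NOT_MEASURED")
  expect_equal(res$total, 5L)
})
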