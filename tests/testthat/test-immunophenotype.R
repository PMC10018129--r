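test_that("phenotype strings split into marker + tag units in written order", {
  p <- parse_phenotype("CD4+FOXP3+CD25hi")
  expect_identical(nrow(p$units), 3L)
  expect_identical(p$units$marker, c("CD4", "FOXP3", "CD25"))
  expect_identical(p$units$tag, c("+", "+", "hi"))

  q <- parse_phenotype("CD45RA+CCR7-")
  expect_identical(q$units$marker, c("CD45RA", "CCR7"))
  expect_identical(q$units$tag, c("+", "-"))

  # Unicode minus is accepted
  expect_identical(parse_phenotype("CCR7−")$units$tag, "-")
  # adjacent graded and signed units separate cleanly
  two <- parse_phenotype("CD25hiCD4+")
  expect_identical(two$units$marker, c("CD25", "CD4"))
  # hyphenated marker names need the lexicon to beat the minus-tag reading
  lex <- alias_map(c(`HLA-DR` = "HLA-DRA"))
  h <- parse_phenotype("HLA-DR+CD25lo", aliases = lex)
  expect_identical(h$units$marker, c("HLA-DR", "CD25"))
  expect_identical(normalize_phenotype(h, lex)$units$marker,
                   c("HLA-DRA", "CD25"))
  bare <- parse_phenotype("HLA-DR+")
  expect_identical(bare$units$marker, c("HLA", "DR"))
  # graded tags are kept distinct
  expect_identical(parse_phenotype("CD26high")$units$tag, "high")
  expect_identical(parse_phenotype("CD26hi")$units$tag, "hi")

  expect_error(parse_phenotype("CD4"), "cannot parse")
  expect_error(parse_phenotype(""), "empty")
})

test_that("serialization and parsing are mutually inverse on canonical forms", {
  for (s in c("CD4+FOXP3+CD25hi", "CD45RA+CCR7-", "A1-B2+C3int",
              "CD8A+CD8B+CD3D+")) {
    p <- parse_phenotype(s)
    expect_identical(format(parse_phenotype(format(p))), format(p))
  }
})

test_that("alias normalization maps to standard symbols order-independently", {
  a <- alias_map(c(CD26 = "DPP4", CD49f = "ITGA6", CD25 = "IL2RA"))
  p <- normalize_phenotype(parse_phenotype("CD26+CD49f-"), a)
  expect_identical(p$units$marker, c("DPP4", "ITGA6"))
  expect_identical(p$units$tag, c("+", "-"))

  k1 <- normalize_phenotype(parse_phenotype("CD4+CD25hi"), a)
  k2 <- normalize_phenotype(parse_phenotype("CD25hiCD4+"), a)
  expect_identical(k1$canonical_key, k2$canonical_key)

  # same symbol with conflicting tags after mapping is contradictory
  expect_error(normalize_phenotype(parse_phenotype("CD26+DPP4-"), a),
               "conflicting tags")
  # identical tags merge instead
  merged <- normalize_phenotype(parse_phenotype("CD26+DPP4+"), a)
  expect_identical(nrow(merged$units), 1L)

  # idempotence; unresolvable markers are flagged, not fatal
  u <- normalize_phenotype(parse_phenotype("XYZZY+CD26+"), a)
  expect_identical(u$unmapped, "XYZZY")
  expect_identical(format(normalize_phenotype(u, a)), format(u))
})

test_that("layer splitting enumerates nonredundant unit subsets", {
  p <- parse_phenotype("CD4+FOXP3+CD25hi")
  kids <- split_layers(p, 2)
  expect_length(kids, 3L)
  expect_setequal(vapply(kids, format, character(1L)),
                  c("CD4+FOXP3+", "FOXP3+CD25hi", "CD4+CD25hi"))

  expect_identical(format(split_layers(p, 3)[[1L]]), format(p))
  expect_setequal(vapply(split_layers(p, 1), format, character(1L)),
                  c("CD4+", "FOXP3+", "CD25hi"))
  expect_error(split_layers(p, 4), "between 1 and 3")

  # |split_layers(p, k)| = C(n, k) for distinct symbols
  big <- parse_phenotype("A+B-C+D-E+")
  for (k in 1:5)
    expect_length(split_layers(big, k), choose(5, k))
})

test_that("state enumeration spans all 2^n signed combinations", {
  two <- enumerate_states(c("CCR7", "DPP4"))
  expect_length(two, 4L)
  three <- enumerate_states(c("CCR7", "DPP4", "ITGA6"))
  expect_length(three, 8L)
  keys <- vapply(three, `[[`, character(1L), "canonical_key")
  expect_identical(anyDuplicated(keys), 0L)

  one <- enumerate_states("G")
  expect_setequal(vapply(one, format, character(1L)), c("G+", "G-"))
  expect_error(enumerate_states(c("A", "A")), "duplicate")
})

test_that("plasticity support requires every member gene above the cutoff", {
  stats <- data.frame(gene = c("A", "B", "C"),
                      gpl_abs_array = c(80, 30, 60),
                      gpl_abs_rnaseq = c(70, 20, 40))
  ab <- parse_phenotype("A+B-")
  ac <- parse_phenotype("A+C-")
  expect_false(layer_support(ab, stats)$supported)
  expect_true(layer_support(ac, stats)$supported)          # either: C = 60
  expect_false(layer_support(ac, stats, mode = "both")$supported)
  expect_true(layer_support(ab, stats, cutoff = 0)$supported)

  missing <- layer_support(parse_phenotype("A+Z-"), stats)
  expect_false(missing$supported)
  expect_identical(missing$missing, "Z")
})

test_that("corpus statistics deduplicate phenotypes, markers and layers globally", {
  corpus <- lapply(c("A+B+", "B+A+", "A+B+C-"), parse_phenotype)
  cs <- corpus_stats(corpus)
  expect_identical(cs$n_phenotypes, 2L)
  expect_identical(cs$markers, c("A", "B", "C"))
  # layer-2 children: {A+B+} from both parents, plus {B+C-}, {A+C-}
  expect_identical(cs$n_layer2, 3L)
  expect_identical(cs$n_layer3, 1L)

  empty <- corpus_stats(list())
  expect_identical(empty$n_phenotypes, 0L)
  expect_length(empty$markers, 0L)
})

test_that("candidate extraction finds sign- and label-tagged phenotypes near cell mentions", {
  hits <- extract_candidates(
    "sorted CD45RA+CCR7- T cells were profiled")
  expect_gte(nrow(hits), 1L)
  expect_true(any(grepl("CD45RA+CCR7-", hits$match, fixed = TRUE)))

  expect_identical(nrow(extract_candidates("plain prose about cells")), 0L)

  lab <- extract_candidates("the CD25hi B cells expanded")
  expect_true(any(grepl("CD25hi", lab$match, fixed = TRUE)))

  # Unicode minus is normalized before matching
  uni <- extract_candidates("CD8− T cells declined")
  expect_gte(nrow(uni), 1L)
})

test_that("synthetic marker corpora parse and normalize completely", {
  corpus <- generate_marker_corpus(n_phenotypes = 150L, seed = 91L)
  parsed <- lapply(corpus$phenotypes, parse_phenotype)
  normed <- lapply(parsed, normalize_phenotype, a = corpus$aliases)
  expect_true(all(vapply(normed, function(p) length(p$unmapped) == 0L,
                         logical(1L))))
  cs <- corpus_stats(normed)
  expect_true(all(cs$markers %in% corpus$truth$marker))
  # the unit-count distribution concentrates at three genes or fewer
  small <- sum(cs$unit_histogram[as.integer(names(cs$unit_histogram)) <= 3])
  expect_gt(small / cs$n_phenotypes, 0.75)
})
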