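tabs <- test_tables()

test_that("string similarity metrics are normalized and symmetric", {
  metrics <- c("levenshtein", "jaro_winkler", "smith_waterman",
               "monge_elkan", "soft_tfidf")
  for (m in metrics) {
    expect_equal(string_similarity("abc", "abc", m), 1.0)
  }
  expect_equal(string_similarity("abc", "abd", "levenshtein"), 1 - 1 / 3)
  expect_error(string_similarity("abc", "abd", "nope"))
  expect_error(string_similarity("", "abc", "levenshtein"))
  set.seed(404)
  for (i in 1:20) {
    a <- paste(sample(letters[1:5], sample(2:8, 1), TRUE), collapse = "")
    b <- paste(sample(letters[1:5], sample(2:8, 1), TRUE), collapse = "")
    for (m in metrics) {
      sab <- string_similarity(a, b, m)
      expect_equal(sab, string_similarity(b, a, m), info = m)
      expect_gte(sab, 0)
      expect_lte(sab, 1)
    }
  }
})

test_that("smith-waterman rewards local alignment", {
  # "ypk" aligns fully inside "xypkz": score 6 over 2*min(3,5)
  expect_equal(string_similarity("ypk", "xypkz", "smith_waterman"), 1.0)
  expect_lt(string_similarity("abcd", "abxd", "smith_waterman"), 1.0)
})

test_that("synonym features extract the documented fields", {
  f <- synonym_features("YPK1", tabs)
  expect_identical(f$prefix3, "ypk")
  expect_identical(f$suffix3, "pk1")
  expect_identical(f$number_part, "1")
  expect_identical(f$greek_part, "")
  short <- synonym_features("ab", tabs)
  expect_identical(short$prefix3, "ab")
  expect_identical(short$suffix3, "ab")
  expect_identical(synonym_features("TNF-alpha", tabs)$greek_part, "alpha")
  expect_identical(synonym_features("TNFalpha", tabs)$greek_part, "alpha")
  expect_identical(synonym_features("IL6", tabs)$shape, "AA1")
})

test_that("pair features compare feature vectors symmetrically", {
  cfg <- matcher_config()
  f <- synonym_features("YPK1", tabs)
  self <- pair_features(f, f, cfg)
  expect_true(self$equal_prefix && self$equal_suffix &&
              self$equal_number && self$equal_greek)
  expect_equal(self$bigram_sim, 1.0)
  expect_equal(self$string_sim, 1.0)
  expect_equal(self$shape_sim, 1.0)
  g <- synonym_features("YPK2", tabs)
  fg <- pair_features(f, g, cfg)
  expect_true(fg$equal_prefix)
  expect_false(fg$equal_number)
  gf <- pair_features(g, f, cfg)
  for (field in setdiff(names(fg), "label")) {
    expect_equal(fg[[field]], gf[[field]], info = field)
  }
  disjoint <- pair_features(synonym_features("aaaa", tabs),
                            synonym_features("zzzz", tabs), cfg)
  expect_equal(disjoint$bigram_sim, 0.0)
})

test_that("candidate pairs select by n-gram similarity and label by gene", {
  store <- toy_store(tabs)
  cfg <- matcher_config(pct_similarity = 0.5, seed = 3)
  pairs <- candidate_pairs(store, cfg)
  expect_true(all(pairs$s1 != pairs$s2))
  # hyphen variant pair: Dice(tnf alpha, tnf-alpha) = 12/16 = 0.75
  key <- paste(pairs$s1, pairs$s2)
  expect_true("TNF alpha TNF-alpha" %in% key ||
              "TNF-alpha TNF alpha" %in% key)
  lab <- pairs$label[key %in% c("TNF alpha TNF-alpha",
                                "TNF-alpha TNF alpha")]
  expect_true(all(lab))
  # same-gene requirement: cross-gene near pairs are negative
  expect_false(any(pairs$label[
    (pairs$s1 %in% c("YPK1", "YPK-1", "ypk1")) !=
    (pairs$s2 %in% c("YPK1", "YPK-1", "ypk1"))]))
  # a dictionary with no near-duplicate pair has no positives at pct 1
  plain <- data.frame(gene_id = c("1", "2"), taxon_id = "9606",
                      symbol = c("ABCD", "WXYZ"),
                      synonyms = I(list("ABCD", "WXYZ")),
                      stringsAsFactors = FALSE)
  expect_error(
    candidate_pairs(build_dictionary(plain, tabs),
                    matcher_config(pct_similarity = 1)),
    "lower the threshold")
})

test_that("raising the selection threshold never adds candidate pairs", {
  spec <- fixture_spec(seed = 13, n_genes = 12, n_synonyms_per_gene = 4)
  d <- synth_dictionary(spec)
  recs <- load_gene_info(text = d$gene_info, taxon_id = d$taxon_id)
  store <- build_dictionary(recs, tabs)
  counts <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(p) {
    nrow(candidate_pairs(store, matcher_config(
      pct_similarity = p, negative_ratio = 10000L, seed = 13)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("training is deterministic under a fixed seed", {
  store <- toy_store(tabs)
  cfg <- matcher_config(pct_similarity = 0.5, seed = 11)
  p1 <- candidate_pairs(store, cfg)
  p2 <- candidate_pairs(store, cfg)
  expect_identical(p1, p2)
  m1 <- train_matcher(store, cfg, tabs)
  m2 <- train_matcher(store, cfg, tabs)
  X <- genenorm:::pair_feature_matrix(p1$s1, p1$s2, tabs, cfg)
  expect_identical(
    genenorm:::predict_classifier(m1$fit, X, cfg$algorithm),
    genenorm:::predict_classifier(m2$fit, X, cfg$algorithm))
  expect_identical(m1$fit$SV, m2$fit$SV)
})

test_that("all three classifiers train and predict on the pair stream", {
  spec <- fixture_spec(seed = 21, n_genes = 15, n_synonyms_per_gene = 4)
  d <- synth_dictionary(spec)
  recs <- load_gene_info(text = d$gene_info, taxon_id = d$taxon_id)
  store <- build_dictionary(recs, tabs)
  for (alg in c("svm", "random_forest", "logistic_regression")) {
    cfg <- matcher_config(pct_similarity = 0.8, algorithm = alg, seed = 21)
    ev <- evaluate_matcher(store, cfg, tables = tabs)
    expect_gte(ev$accuracy, ev$baseline, label = alg)
  }
})

test_that("ml matching recovers punctuation and case variants", {
  spec <- fixture_spec(seed = 31, n_genes = 15, n_synonyms_per_gene = 4)
  d <- synth_dictionary(spec)
  recs <- load_gene_info(text = d$gene_info, taxon_id = d$taxon_id)
  store <- build_dictionary(recs, tabs)
  cfg <- matcher_config(pct_similarity = 0.8, seed = 31)
  model <- train_matcher(store, cfg, tabs)
  # a stored synonym matches itself
  syn <- recs$synonyms[[1]][1]
  expect_true(recs$gene_id[1] %in% ml_match(syn, store, model, tabs)$gene_id)
  # punctuation-perturbed mention still reaches its gene
  hyphenated <- sub("([0-9]+)$", "-\\1", syn)
  expect_true(recs$gene_id[1] %in%
              ml_match(hyphenated, store, model, tabs)$gene_id)
  # no n-gram overlap, no candidates
  expect_identical(nrow(ml_match("zzzz", store, model, tabs)), 0L)
  # a model cannot be applied under a different config
  other <- matcher_config(pct_similarity = 0.7, seed = 31)
  expect_error(ml_match(syn, store, model, tabs, config = other),
               "different matcher_config")
})

test_that("matcher model persistence round-trips", {
  store <- toy_store(tabs)
  cfg <- matcher_config(pct_similarity = 0.5, seed = 2)
  model <- train_matcher(store, cfg, tabs)
  dir <- withr::local_tempdir()
  save_matcher(model, dir)
  back <- load_matcher(dir)
  expect_identical(back$config, model$config)
  expect_identical(
    ml_match("TNF alpha", store, back, tabs),
    ml_match("TNF alpha", store, model, tabs))
})
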