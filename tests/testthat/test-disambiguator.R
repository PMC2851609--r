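tabs <- test_tables()

gene_doc <- function(id, tokens) {
  structure(list(gene_id = id, tokens = tokens), class = "gene_document")
}

mention_with <- function(candidate_ids) {
  cand <- data.frame(gene_id = candidate_ids,
                     matched_synonym = candidate_ids,
                     score = 0, selected = FALSE, stringsAsFactors = FALSE)
  data.frame(text = "m", start = 0L, end = 0L,
             candidates = I(list(cand)), stringsAsFactors = FALSE)
}

test_that("gene-documents compile tokenized, filtered field text", {
  rec <- data.frame(gene_id = "1", taxon_id = "9606", symbol = "TNF",
                    synonyms = I(list("TNF")), stringsAsFactors = FALSE)
  expect_identical(build_gene_document(rec, NULL, tabs)$tokens, "tnf")
  rows <- data.frame(field = c("summary", "go"),
                     text = c("tumor necrosis factor", "cytokine activity"),
                     stringsAsFactors = FALSE)
  doc <- build_gene_document(rec, rows, tabs)
  expect_true(all(c("necrosis", "cytokine") %in% doc$tokens))
  # stopwords are removed from document bags
  rows2 <- data.frame(field = "summary", text = "the and of",
                      stringsAsFactors = FALSE)
  expect_identical(build_gene_document(rec, rows2, tabs)$tokens, "tnf")
})

test_that("candidate scoring implements cosine, common tokens and product", {
  a <- c("a", "b", "c", "c")
  doc <- gene_doc("1", c("b", "c"))
  expect_equal(score_candidate(a, doc, "common_tokens"), 2)
  expect_equal(score_candidate(a, doc, "cosine"), 3 / (sqrt(6) * sqrt(2)))
  expect_equal(score_candidate(a, doc, "product"),
               2 * 3 / (sqrt(6) * sqrt(2)))
  expect_equal(score_candidate(a, gene_doc("1", a), "cosine"), 1.0)
  expect_equal(score_candidate(a, gene_doc("1", c("x", "y")), "product"), 0)
  expect_equal(score_candidate(a, gene_doc("1", character(0)), "cosine"), 0)
  # cosine is invariant to duplicating both bags; common tokens to
  # within-bag duplication
  expect_equal(score_candidate(rep(a, 2), gene_doc("1", rep(c("b", "c"), 2)),
                               "cosine"),
               score_candidate(a, doc, "cosine"))
  expect_equal(score_candidate(c(a, a), doc, "common_tokens"), 2)
})

test_that("the selection rule keeps the argmax / the 50%-of-max set", {
  scores <- c(0.9, 0.7, 0.5, 0.4)
  multi <- select_candidates(scores, "multiple")
  expect_equal(multi$threshold, 0.45)
  expect_identical(multi$selected, c(TRUE, TRUE, TRUE, FALSE))
  single <- select_candidates(scores, "single")
  expect_identical(single$selected, c(TRUE, FALSE, FALSE, FALSE))
  # ties in single mode keep all tied candidates
  expect_identical(select_candidates(c(0.5, 0.5, 0.1), "single")$selected,
                   c(TRUE, TRUE, FALSE))
  # all-zero scores in multiple mode select everything
  expect_identical(select_candidates(c(0, 0), "multiple")$selected,
                   c(TRUE, TRUE))
})

test_that("selection is invariant to positive scaling of scores", {
  set.seed(505)
  for (i in 1:20) {
    scores <- runif(sample(2:6, 1))
    k <- runif(1, 0.1, 10)
    for (mode in c("single", "multiple")) {
      expect_identical(select_candidates(scores, mode)$selected,
                       select_candidates(scores * k, mode)$selected)
    }
  }
})

test_that("multiple-mode selection contains the single-mode selection", {
  set.seed(606)
  for (i in 1:20) {
    scores <- round(runif(sample(2:6, 1)), 2)
    s <- select_candidates(scores, "single")$selected
    m <- select_candidates(scores, "multiple")$selected
    expect_true(all(m[s]))
    expect_true(any(m & scores == max(scores)))
  }
})

test_that("disambiguation fills scores and selection flags per mention", {
  docs <- list(
    "1" = gene_doc("1", c("kinase", "signal", "stress")),
    "2" = gene_doc("2", c("ribosome", "translation")))
  article <- "kinase signal cascade under stress"
  m0 <- data.frame(text = "m", start = 0L, end = 0L,
                   candidates = I(list(
                     data.frame(gene_id = character(),
                                matched_synonym = character(),
                                score = numeric(), selected = logical(),
                                stringsAsFactors = FALSE))),
                   stringsAsFactors = FALSE)
  out0 <- disambiguate(m0, article, docs, disambiguation_config(), tabs)
  expect_identical(nrow(out0$candidates[[1]]), 0L)

  m1 <- mention_with("2")
  out1 <- disambiguate(m1, article, docs, disambiguation_config(), tabs)
  expect_true(out1$candidates[[1]]$selected)
  expect_equal(out1$candidates[[1]]$score, 0)  # one candidate: no scoring

  m2 <- mention_with(c("1", "2"))
  out2 <- disambiguate(m2, article, docs,
                       disambiguation_config("product", "single"), tabs)
  cand <- out2$candidates[[1]]
  expect_identical(cand$gene_id[1], "1")  # ordered by descending score
  expect_true(cand$selected[1])
  expect_false(cand$selected[2])
  expect_gt(cand$score[1], 0)

  expect_warning(
    disambiguate(mention_with(c("1", "404")), article, docs,
                 disambiguation_config(), tabs),
    "404")
})

test_that("normalize_mentions runs flexible matching end to end", {
  store <- toy_store(tabs)
  text <- "We studied TNF alpha signaling."
  mentions <- data.frame(text = "TNF alpha", start = 9L, end = 16L,
                         stringsAsFactors = FALSE)
  out <- normalize_mentions(mentions, text, store, tabs)
  cand <- out$candidates[[1]]
  expect_identical(cand$gene_id, "101")
  expect_true(cand$selected)
  tab <- normalization_table(out, "S1")
  expect_identical(tab$gene_id, "101")
  expect_identical(names(tab),
                   c("sentence_id", "start", "end", "mention", "gene_id",
                     "matched_synonym", "score", "selected"))
})
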