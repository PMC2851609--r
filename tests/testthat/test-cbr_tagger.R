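tabs <- test_tables()

one_sentence_corpus <- function() {
  sentences <- data.frame(sentence_id = "S1", text = "TNF binds",
                          stringsAsFactors = FALSE)
  annotations <- data.frame(sentence_id = "S1", start = 0L, end = 2L,
                            text = "TNF", stringsAsFactors = FALSE)
  list(sentences = sentences, annotations = annotations)
}

test_that("training upserts one known case per token with gold categories", {
  c1 <- one_sentence_corpus()
  base <- train_tagger(c1$sentences, c1$annotations, tabs, "t")
  k <- base$known
  expect_true(any(k$token_text == "TNF" & k$category & !k$prev_category &
                  k$frequency == 1L))
  expect_true(any(k$token_text == "binds" & !k$category & k$prev_category &
                  k$frequency == 1L))
  # repeating the corpus increments frequencies, not case counts
  sent2 <- rbind(c1$sentences,
                 within(c1$sentences, sentence_id <- "S2"))
  ann2 <- rbind(c1$annotations,
                within(c1$annotations, sentence_id <- "S2"))
  base2 <- train_tagger(sent2, ann2, tabs, "t")
  expect_identical(nrow(base2$known), nrow(base$known))
  expect_identical(base2$known$frequency, base$known$frequency * 2L)
})

test_that("training validates ids and tolerates an empty corpus", {
  c1 <- one_sentence_corpus()
  bad <- within(c1$annotations, sentence_id <- "NOPE")
  expect_error(train_tagger(c1$sentences, bad, tabs, "t"), "NOPE")
  expect_warning(
    base <- train_tagger(c1$sentences[0, ], c1$annotations[0, ], tabs, "t"),
    "empty")
  expect_identical(nrow(base$known), 0L)
  expect_identical(nrow(base$unknown), 0L)
})

test_that("merging case bases sums frequencies of identical cases", {
  c1 <- one_sentence_corpus()
  base <- train_tagger(c1$sentences, c1$annotations, tabs, "t")
  empty <- suppressWarnings(
    train_tagger(c1$sentences[0, ], c1$annotations[0, ], tabs, "e"))
  expect_identical(merge_cases(base, empty)$known, base$known)
  both <- merge_cases(base, base)
  expect_identical(both$known$frequency, base$known$frequency * 2L)
  expect_identical(merge_cases(base, empty)$known,
                   merge_cases(empty, base, "t")$known)
})

test_that("classification prefers known cases and higher frequencies", {
  # shape Aa1 seen 3x as gene, 7x as non-gene (prev = FALSE)
  sent <- data.frame(
    sentence_id = c("A", "B"),
    text = c(paste(rep("Abc1", 3), collapse = " ; "),
             paste(rep("Def2", 7), collapse = " ; ")),
    stringsAsFactors = FALSE)
  ann <- do.call(rbind, lapply(0:2, function(k) {
    data.frame(sentence_id = "A", start = k * 5L, end = k * 5L + 3L,
               text = "Abc1", stringsAsFactors = FALSE)
  }))
  base <- train_tagger(sent, ann, tabs, "t")
  # known retrieval: unique match wins regardless of shape statistics
  expect_true(classify_token("Abc1", FALSE, base, tabs))
  expect_false(classify_token("Def2", FALSE, base, tabs))
  # unseen token falls back to the shape base: 7 negative > 3 positive
  expect_false(classify_token("Ghi3", FALSE, base, tabs))
  # nothing retrieved anywhere: default negative
  expect_false(classify_token("zzz", TRUE, base, tabs))
})

test_that("sub-splitting classifies token parts individually", {
  c1 <- one_sentence_corpus()
  base <- train_tagger(c1$sentences, c1$annotations, tabs, "t")
  # "TNF/x" is unseen and has no stored shape, but its part "TNF" is a
  # known positive case
  expect_true(classify_token("TNF/x", FALSE, base, tabs))
})

test_that("tagging memorizes its training corpus", {
  c1 <- one_sentence_corpus()
  base <- train_tagger(c1$sentences, c1$annotations, tabs, "t")
  m <- tag("TNF binds", base, tabs)
  expect_identical(m$text, "TNF")
  expect_identical(c(m$start, m$end), c(0L, 2L))
  expect_identical(nrow(tag("", base, tabs)), 0L)

  spec <- fixture_spec(seed = 5, n_genes = 8, n_synonyms_per_gene = 3,
                       n_sentences = 40)
  d <- synth_dictionary(spec)
  recs <- load_gene_info(text = d$gene_info, taxon_id = d$taxon_id)
  corp <- synth_corpus(spec, recs)
  base <- train_tagger(corp$sentences, corp$annotations, tabs, "fix")
  out <- tag_corpus(corp$sentences, base, tabs)
  expect_identical(write_annotations(out),
                   write_annotations(corp$annotations))
})

test_that("emitted mentions satisfy the offset length invariant", {
  spec <- fixture_spec(seed = 6, n_genes = 5, n_synonyms_per_gene = 3,
                       n_sentences = 15)
  d <- synth_dictionary(spec)
  recs <- load_gene_info(text = d$gene_info, taxon_id = d$taxon_id)
  corp <- synth_corpus(spec, recs)
  base <- train_tagger(corp$sentences, corp$annotations, tabs, "fix")
  out <- tag_corpus(corp$sentences, base, tabs)
  expect_gt(nrow(out), 0L)
  expect_identical(out$end - out$start + 1L,
                   nchar(gsub(" ", "", out$text, fixed = TRUE)))
})

test_that("case-base persistence round trip preserves tagging output", {
  spec <- fixture_spec(seed = 9, n_genes = 6, n_synonyms_per_gene = 3,
                       n_sentences = 20)
  d <- synth_dictionary(spec)
  recs <- load_gene_info(text = d$gene_info, taxon_id = d$taxon_id)
  corp <- synth_corpus(spec, recs)
  base <- train_tagger(corp$sentences, corp$annotations, tabs, "persist")
  dir <- withr::local_tempdir()
  save_case_base(base, dir)
  loaded <- load_case_base(dir, "persist")
  expect_identical(loaded$known, base$known)
  expect_identical(loaded$unknown, base$unknown)
  expect_identical(
    write_annotations(tag_corpus(corp$sentences, loaded, tabs)),
    write_annotations(tag_corpus(corp$sentences, base, tabs)))
})

test_that("tagging is deterministic", {
  c1 <- one_sentence_corpus()
  base <- train_tagger(c1$sentences, c1$annotations, tabs, "t")
  expect_identical(tag("TNF binds TNF", base, tabs),
                   tag("TNF binds TNF", base, tabs))
})
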