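# Trainable approximate matcher. Synonyms are represented by
# synonym-features (prefix, suffix, number part, Greek part, bigrams,
# trigrams, shape); candidate pairs are selected by n-gram similarity;
# pair-features compare two synonym-feature vectors; a binary classifier
# (SVM, random forest or logistic regression) learns which pairs name the
# same gene.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Matcher configuration
#'
#' Defaults follow the method's stated defaults: selection threshold 0.9,
#' bigram-or-trigram selection, SVM classifier, the "best" pair-feature
#' subset (bigram/trigram similarity, number equality, string similarity)
#' and the Smith-Waterman string metric.
#'
#' @param pct_similarity N-gram similarity threshold in \[0, 1\] for
#'   candidate-pair selection.
#' @param gram_selection `"bigram"`, `"trigram"` or `"both"` (a pair
#'   passes when either gram similarity reaches the threshold).
#' @param algorithm `"svm"`, `"random_forest"` or
#'   `"logistic_regression"`.
#' @param feature_set `"best"` or `"all"`.
#' @param string_metric Metric name passed to [string_similarity()].
#' @param negative_ratio Negatives kept per positive when subsampling the
#'   training pairs.
#' @param seed Integer seed driving subsampling and classifier fitting.
#' @return An object of class `matcher_config`.
#' @export
matcher_config <- function(pct_similarity = 0.9,
                           gram_selection = c("both", "bigram", "trigram"),
                           algorithm = c("svm", "random_forest",
                                         "logistic_regression"),
                           feature_set = c("best", "all"),
                           string_metric = "smith_waterman",
                           negative_ratio = 3L,
                           seed = 1L) {
  stopifnot(pct_similarity >= 0, pct_similarity <= 1,
            negative_ratio >= 1L)
  string_metric <- match.arg(string_metric,
                             c("levenshtein", "jaro_winkler",
                               "smith_waterman", "monge_elkan",
                               "soft_tfidf"))
  structure(list(pct_similarity = pct_similarity,
                 gram_selection = match.arg(gram_selection),
                 algorithm = match.arg(algorithm),
                 feature_set = match.arg(feature_set),
                 string_metric = string_metric,
                 negative_ratio = as.integer(negative_ratio),
                 seed = as.integer(seed)),
            class = "matcher_config")
}

#' Synonym feature representation
#'
#' Lowercased 3-letter prefix and suffix (the whole string when shorter),
#' the first maximal digit run, the first Greek-letter name found among
#' the synonym's letter tokens, bigram and trigram multisets of the
#' lowercased text, and the plain token shape (per token for multiword
#' synonyms, joined by spaces).
#'
#' @param text Non-empty synonym or mention string.
#' @param tables Symbol tables.
#' @return A list of class `synonym_features`.
#' @export
synonym_features <- function(text, tables) {
  stopifnot(nzchar(text))
  lower <- tolower(text)
  n <- nchar(lower)
  num <- regmatches(text, regexpr("[0-9]+", text))
  words <- strsplit(text, "[^[:alpha:]]+")[[1]]
  words <- words[nzchar(words)]
  greek_part <- ""
  for (w in words) {
    cand <- split_greek_word(w, tables$greek_letters)
    hit <- tolower(cand)[tolower(cand) %in% tables$greek_letters]
    if (length(hit)) {
      greek_part <- hit[1]
      break
    }
  }
  toks <- ws_tokens(text)
  shape <- paste(vapply(toks, function(t) shape_of(t, tables)$plain, ""),
                 collapse = " ")
  structure(list(
    text = text,
    prefix3 = substr(lower, 1L, min(3L, n)),
    suffix3 = substr(lower, max(1L, n - 2L), n),
    number_part = if (length(num)) num else "",
    greek_part = greek_part,
    bigrams = table(ngrams(lower, 2L)),
    trigrams = table(ngrams(lower, 3L)),
    shape = shape
  ), class = "synonym_features")
}

# Unique synonym strings of a store with the set of genes carrying each.
store_synonyms <- function(store) {
  syn <- unlist(store$records$synonyms)
  gene <- rep(store$records$gene_id,
              vapply(store$records$synonyms, length, 1L))
  genes_by_syn <- split(gene, syn)
  syns <- sort(names(genes_by_syn), method = "radix")
  list(synonyms = syns, genes = genes_by_syn[syns])
}

# N-gram pass rule for one pair under a config.
gram_pass <- function(b2, b3, config) {
  switch(config$gram_selection,
    bigram = b2 >= config$pct_similarity,
    trigram = b3 >= config$pct_similarity,
    both = b2 >= config$pct_similarity || b3 >= config$pct_similarity)
}

#' Candidate synonym pairs for matcher training
#'
#' Emits every unordered pair of distinct synonym strings whose selected
#' n-gram similarity reaches `pct_similarity`. A pair is positive when the
#' two synonyms share a gene, else negative; negatives are subsampled to
#' `negative_ratio` per positive using the config seed.
#'
#' @param store A `dictionary_store`.
#' @param config A `matcher_config`.
#' @return A data.frame (`s1`, `s2`, `bigram_sim`, `trigram_sim`,
#'   `label`) with logical `label`.
#' @export
candidate_pairs <- function(store, config = matcher_config()) {
  ss <- store_synonyms(store)
  syns <- ss$synonyms
  m <- length(syns)
  if (m < 2L) stop("dictionary holds fewer than two distinct synonyms")
  g2 <- lapply(syns, function(s) table(ngrams(s, 2L)))
  g3 <- lapply(syns, function(s) table(ngrams(s, 3L)))
  rows <- vector("list", m - 1L)
  for (i in seq_len(m - 1L)) {
    j <- (i + 1L):m
    b2 <- vapply(j, function(k) dice_tables(g2[[i]], g2[[k]]), numeric(1))
    b3 <- vapply(j, function(k) dice_tables(g3[[i]], g3[[k]]), numeric(1))
    pass <- vapply(seq_along(j), function(k) gram_pass(b2[k], b3[k], config),
                   logical(1))
    if (!any(pass)) next
    jj <- j[pass]
    rows[[i]] <- data.frame(
      s1 = syns[i], s2 = syns[jj],
      bigram_sim = b2[pass], trigram_sim = b3[pass],
      label = vapply(jj, function(k) {
        length(intersect(ss$genes[[i]], ss$genes[[k]])) > 0L
      }, logical(1)),
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, rows)
  n_pos <- if (is.null(pairs)) 0L else sum(pairs$label)
  if (n_pos == 0L) {
    stop("no positive synonym pairs at pct_similarity = ",
         config$pct_similarity, "; lower the threshold")
  }
  neg_idx <- which(!pairs$label)
  keep_neg <- min(length(neg_idx), config$negative_ratio * n_pos)
  if (keep_neg < length(neg_idx)) {
    neg_idx <- with_seed(config$seed, sort(sample(neg_idx, keep_neg)))
  }
  pairs <- pairs[sort(c(which(pairs$label), neg_idx)), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Pair features comparing two synonym representations
#'
#' Equality indicators for prefix, suffix, number and Greek parts (empty
#' equals empty), bigram and trigram Dice similarity, string similarity
#' under the configured metric, and shape similarity (normalized edit
#' similarity between the shape strings).
#'
#' @param fa,fb `synonym_features` objects.
#' @param config A `matcher_config`.
#' @param corpus Optional corpus for the `soft_tfidf` metric.
#' @return A list of class `pair_features` with `label = NA`.
#' @export
pair_features <- function(fa, fb, config = matcher_config(), corpus = NULL) {
  shape_sim <- 1 - drop(utils::adist(fa$shape, fb$shape)) /
    max(nchar(fa$shape), nchar(fb$shape))
  structure(list(
    equal_prefix = identical(fa$prefix3, fb$prefix3),
    equal_suffix = identical(fa$suffix3, fb$suffix3),
    equal_number = identical(fa$number_part, fb$number_part),
    equal_greek = identical(fa$greek_part, fb$greek_part),
    bigram_sim = dice_tables(fa$bigrams, fb$bigrams),
    trigram_sim = dice_tables(fa$trigrams, fb$trigrams),
    string_sim = string_similarity(fa$text, fb$text, config$string_metric,
                                   corpus = corpus),
    shape_sim = shape_sim,
    label = NA
  ), class = "pair_features")
}

matcher_feature_names <- function(feature_set) {
  if (feature_set == "best") {
    c("bigram_sim", "trigram_sim", "equal_number", "string_sim")
  } else {
    c("equal_prefix", "equal_suffix", "equal_number", "equal_greek",
      "bigram_sim", "trigram_sim", "string_sim", "shape_sim")
  }
}

# Numeric feature matrix for a set of synonym string pairs, caching the
# per-synonym feature extraction.
pair_feature_matrix <- function(s1, s2, tables, config, corpus = NULL) {
  cache <- new.env(parent = emptyenv())
  feat <- function(s) {
    key <- paste0("s", s)
    f <- cache[[key]]
    if (is.null(f)) {
      f <- synonym_features(s, tables)
      cache[[key]] <- f
    }
    f
  }
  cols <- matcher_feature_names(config$feature_set)
  X <- matrix(0, nrow = length(s1), ncol = length(cols),
              dimnames = list(NULL, cols))
  for (i in seq_along(s1)) {
    pf <- pair_features(feat(s1[i]), feat(s2[i]), config, corpus)
    X[i, ] <- vapply(pf[cols], as.numeric, numeric(1))
  }
  X
}

fit_classifier <- function(X, y, config) {
  y <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  if (length(unique(y)) < 2L) {
    stop("degenerate single-class training set; cannot fit a classifier")
  }
  with_seed(config$seed, switch(config$algorithm,
    svm = suppressWarnings(e1071::svm(X, y, kernel = "radial")),
    random_forest = randomForest::randomForest(X, y, ntree = 200L),
    logistic_regression = {
      df <- data.frame(X, y = y)
      suppressWarnings(stats::glm(y ~ ., data = df,
                                  family = stats::binomial()))
    }
  ))
}

predict_classifier <- function(fit, X, algorithm) {
  if (algorithm == "logistic_regression") {
    p <- stats::predict(fit, newdata = as.data.frame(X), type = "response")
    unname(p > 0.5)
  } else {
    unname(stats::predict(fit, X) == "pos")
  }
}

#' Train the approximate matcher on a dictionary
#'
#' Generates the labeled candidate-pair stream, extracts pair features and
#' fits the configured classifier. Deterministic given the config seed.
#'
#' @param store A `dictionary_store`.
#' @param config A `matcher_config`.
#' @param tables Symbol tables.
#' @return An object of class `matcher_model` holding the fit, the config
#'   it was trained with, the taxon id and the pair stream used.
#' @export
train_matcher <- function(store, config = matcher_config(),
                          tables = symbol_tables()) {
  pairs <- candidate_pairs(store, config)
  corpus <- if (config$string_metric == "soft_tfidf") {
    store_synonyms(store)$synonyms
  }
  X <- pair_feature_matrix(pairs$s1, pairs$s2, tables, config, corpus)
  fit <- fit_classifier(X, pairs$label, config)
  structure(list(fit = fit, config = config, taxon_id = store$taxon_id,
                 feature_names = colnames(X), n_pairs = nrow(pairs),
                 corpus = corpus),
            class = "matcher_model")
}

#' @export
print.matcher_model <- function(x, ...) {
  cat(sprintf(
    "matcher_model (taxon %s): %s on %d pairs, pct %.2f, metric %s\n",
    x$taxon_id, x$config$algorithm, x$n_pairs,
    x$config$pct_similarity, x$config$string_metric))
  invisible(x)
}

check_model_config <- function(model, config) {
  if (!is.null(config) && !identical(unclass(config), unclass(model$config))) {
    stop("model was trained under a different matcher_config; ",
         "retrain or pass the model's own config")
  }
}

#' Match a mention with a trained matcher
#'
#' The mention is featurized; candidate synonyms are selected by n-gram
#' similarity at the model's threshold; every surviving mention-synonym
#' pair is featurized and classified, and each positive classification
#' contributes the synonym's gene(s) as candidates.
#'
#' @param mention_text The mention's surface string.
#' @param store A `dictionary_store`.
#' @param model A `matcher_model` trained on a compatible store.
#' @param tables Symbol tables.
#' @param config Optional config; must equal the model's training config.
#' @return A candidate data.frame (`gene_id`, `matched_synonym`, `score`,
#'   `selected`), possibly empty.
#' @export
ml_match <- function(mention_text, store, model, tables, config = NULL) {
  check_model_config(model, config)
  config <- model$config
  empty <- data.frame(gene_id = character(), matched_synonym = character(),
                      score = numeric(), selected = logical(),
                      stringsAsFactors = FALSE)
  ss <- store_synonyms(store)
  gm2 <- table(ngrams(mention_text, 2L))
  gm3 <- table(ngrams(mention_text, 3L))
  b2 <- vapply(ss$synonyms, function(s) {
    dice_tables(gm2, table(ngrams(s, 2L)))
  }, numeric(1))
  b3 <- vapply(ss$synonyms, function(s) {
    dice_tables(gm3, table(ngrams(s, 3L)))
  }, numeric(1))
  pass <- vapply(seq_along(ss$synonyms), function(k) {
    gram_pass(b2[k], b3[k], config)
  }, logical(1))
  if (!any(pass)) return(empty)
  syns <- ss$synonyms[pass]
  X <- pair_feature_matrix(rep(mention_text, length(syns)), syns,
                           tables, config, model$corpus)
  positive <- predict_classifier(model$fit, X, config$algorithm)
  if (!any(positive)) return(empty)
  hit_syns <- syns[positive]
  gene_id <- unlist(ss$genes[hit_syns], use.names = FALSE)
  matched <- rep(hit_syns, vapply(ss$genes[hit_syns], length, 1L))
  keep <- !duplicated(gene_id)
  out <- data.frame(gene_id = gene_id[keep], matched_synonym = matched[keep],
                    score = 0, selected = FALSE, stringsAsFactors = FALSE)
  out[order(out$gene_id, method = "radix"), , drop = FALSE]
}

#' Held-out evaluation of the matcher on a dictionary
#'
#' Splits the labeled candidate-pair stream into train and test portions
#' (seeded), fits the configured classifier on the training portion and
#' reports held-out accuracy next to the majority-class baseline.
#'
#' @param store A `dictionary_store`.
#' @param config A `matcher_config`.
#' @param holdout Fraction of pairs held out for testing.
#' @param tables Symbol tables.
#' @return A list with `accuracy`, `baseline`, `n_train`, `n_test`.
#' @export
evaluate_matcher <- function(store, config = matcher_config(),
                             holdout = 0.3, tables = symbol_tables()) {
  pairs <- candidate_pairs(store, config)
  n <- nrow(pairs)
  test_idx <- with_seed(config$seed + 1L,
                        sort(sample(n, max(1L, round(holdout * n)))))
  train_idx <- setdiff(seq_len(n), test_idx)
  corpus <- if (config$string_metric == "soft_tfidf") {
    store_synonyms(store)$synonyms
  }
  X <- pair_feature_matrix(pairs$s1, pairs$s2, tables, config, corpus)
  fit <- fit_classifier(X[train_idx, , drop = FALSE],
                        pairs$label[train_idx], config)
  pred <- predict_classifier(fit, X[test_idx, , drop = FALSE],
                             config$algorithm)
  truth <- pairs$label[test_idx]
  list(accuracy = mean(pred == truth),
       baseline = max(mean(truth), 1 - mean(truth)),
       n_train = length(train_idx),
       n_test = length(test_idx))
}

#' Save a matcher model
#'
#' The fitted classifier and its config are serialized under `dir`.
#'
#' @param model A `matcher_model`.
#' @param dir Directory to write into.
#' @return The directory, invisibly.
#' @export
save_matcher <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "matcher_model.rds"))
  invisible(dir)
}

#' Load a matcher model saved by [save_matcher()]
#'
#' @param dir Directory of the store.
#' @return A `matcher_model`.
#' @export
load_matcher <- function(dir) {
  readRDS(file.path(dir, "matcher_model.rds"))
}
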