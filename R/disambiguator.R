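# Disambiguation of identifiers. Each gene carries a gene-document — a bag
# of lowercase, stopword-filtered tokens compiled from its symbols,
# aliases, descriptions, summaries, GO annotations and the like. A
# mention's candidates are scored by comparing the article text against
# each candidate's gene-document; the single mode keeps the best
# candidate, the multiple mode keeps all candidates scoring at least 50%
# of the maximum.

#' Disambiguation configuration
#'
#' @param method `"cosine"` (term-frequency cosine between article and
#'   gene-document), `"common_tokens"` (size of the shared token set) or
#'   `"product"` of the two (the default).
#' @param mode `"single"` keeps only the top candidate; `"multiple"`
#'   keeps every candidate scoring at least half of the maximum.
#' @return An object of class `disambiguation_config`. The threshold
#'   fraction is fixed at 0.5.
#' @export
disambiguation_config <- function(method = c("product", "cosine",
                                             "common_tokens"),
                                  mode = c("single", "multiple")) {
  structure(list(method = match.arg(method), mode = match.arg(mode),
                 threshold_fraction = 0.5),
            class = "disambiguation_config")
}

#' Token bag of a free text
#'
#' Tokenizes, lowercases and removes stopwords and pure-punctuation
#' tokens; duplicates are kept (term frequencies matter for the cosine
#' method).
#'
#' @param text A string.
#' @param tables Symbol tables.
#' @return Character vector of tokens.
#' @export
document_tokens <- function(text, tables) {
  toks <- tolower(tokenize(text))
  toks <- toks[grepl("[[:alnum:]]", toks)]
  toks[!toks %in% tables$stopwords]
}

#' Build a gene-document
#'
#' Compiles the record's symbol and synonyms together with any annotation
#' field values (descriptions, summaries, products, phenotypes,
#' interactions, GO names and definitions, ...) into one lowercase,
#' stopword-filtered token bag.
#'
#' @param record One row of a gene record data.frame.
#' @param annotation_rows Optional data.frame with columns `field` and
#'   `text`; missing fields simply contribute nothing.
#' @param tables Symbol tables.
#' @return A list of class `gene_document` with `gene_id` and `tokens`.
#' @export
build_gene_document <- function(record, annotation_rows = NULL, tables) {
  texts <- unique(c(record$symbol, unlist(record$synonyms)))
  if (!is.null(annotation_rows) && nrow(annotation_rows)) {
    texts <- c(texts, annotation_rows$text)
  }
  tokens <- unlist(lapply(texts, document_tokens, tables = tables))
  if (is.null(tokens)) tokens <- character(0)
  structure(list(gene_id = record$gene_id, tokens = tokens),
            class = "gene_document")
}

#' Load a gene-document store from TSV
#'
#' Three TAB-separated columns: `gene_id`, `field`, `text`. Records, when
#' given, contribute their symbols and synonyms to the corresponding
#' documents.
#'
#' @param file Path to the TSV.
#' @param records Optional gene records from [load_gene_info()].
#' @param tables Symbol tables.
#' @param text Alternatively the file content as lines or one string.
#' @return A named list of `gene_document` objects keyed by gene id.
#' @export
load_gene_documents <- function(file = NULL, records = NULL, tables,
                                text = NULL) {
  lines <- read_source_lines(file, text)
  lines <- lines[nzchar(trimws(lines))]
  ann <- if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) < 3L)
    if (length(bad)) {
      stop(sprintf("gene-document line %d: expected gene_id<TAB>field<TAB>text",
                   bad[1]))
    }
    data.frame(gene_id = vapply(parts, `[[`, "", 1L),
               field = vapply(parts, `[[`, "", 2L),
               text = vapply(parts, function(p) {
                 paste(p[-(1:2)], collapse = " ")
               }, ""),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), field = character(),
               text = character(), stringsAsFactors = FALSE)
  }
  ids <- unique(c(ann$gene_id, if (!is.null(records)) records$gene_id))
  docs <- lapply(ids, function(id) {
    rec <- if (!is.null(records) && id %in% records$gene_id) {
      records[records$gene_id == id, , drop = FALSE]
    } else {
      data.frame(gene_id = id, symbol = character(0),
                 synonyms = I(list()), stringsAsFactors = FALSE)
    }
    rows <- ann[ann$gene_id == id, c("field", "text"), drop = FALSE]
    if (nrow(rec)) {
      build_gene_document(rec, rows, tables)
    } else {
      structure(list(gene_id = id,
                     tokens = unlist(lapply(rows$text, document_tokens,
                                            tables = tables))),
                class = "gene_document")
    }
  })
  names(docs) <- ids
  docs
}

#' Score one candidate's gene-document against the article
#'
#' `cosine` is the term-frequency cosine over the union vocabulary,
#' `common_tokens` the number of distinct shared tokens, `product` their
#' product. An empty gene-document (or article) scores 0.
#'
#' @param article_tokens Token bag of the article, from
#'   [document_tokens()].
#' @param doc A `gene_document`.
#' @param method Scoring method name.
#' @return A non-negative number.
#' @export
score_candidate <- function(article_tokens,
                            doc,
                            method = c("product", "cosine",
                                       "common_tokens")) {
  method <- match.arg(method)
  a <- article_tokens
  b <- doc$tokens
  if (!length(a) || !length(b)) return(0)
  common <- length(intersect(unique(a), unique(b)))
  if (method == "common_tokens") return(common)
  ta <- table(a)
  tb <- table(b)
  shared <- intersect(names(ta), names(tb))
  dot <- sum(as.numeric(ta[shared]) * as.numeric(tb[shared]))
  cosine <- dot / (sqrt(sum(as.numeric(ta)^2)) * sqrt(sum(as.numeric(tb)^2)))
  switch(method, cosine = cosine, product = cosine * common)
}

#' Candidate selection rule
#'
#' In single mode the top-scoring candidates are selected (all of them on
#' a tie); in multiple mode every candidate scoring at least 50% of the
#' maximum is selected.
#'
#' @param scores Numeric vector of candidate scores.
#' @param mode `"single"` or `"multiple"`.
#' @return A list with logical `selected` and the numeric `threshold`
#'   applied (`0.5 * max` in multiple mode, `max` in single mode).
#' @examples
#' select_candidates(c(0.9, 0.7, 0.5, 0.4), "multiple")$threshold  # 0.45
#' @export
select_candidates <- function(scores, mode = c("single", "multiple")) {
  mode <- match.arg(mode)
  if (!length(scores)) {
    return(list(selected = logical(0), threshold = NA_real_))
  }
  top <- max(scores)
  threshold <- if (mode == "single") top else 0.5 * top
  list(selected = scores >= threshold, threshold = threshold)
}

#' Disambiguate mention candidates against the article text
#'
#' Mentions with no candidate are returned unchanged; a mention with
#' exactly one candidate keeps it selected with score 0 (no
#' disambiguation performed); with two or more candidates each is scored
#' against its gene-document and the configured selection rule is
#' applied. Candidates are re-ordered by descending score, then gene id.
#'
#' @param mentions A data.frame of mentions with a list column
#'   `candidates` of candidate data.frames (as returned by
#'   [flexible_match()] or [ml_match()]).
#' @param article_text The full text the mentions came from.
#' @param docs Gene-document store: a named list of `gene_document`
#'   objects. A candidate without a document scores 0 (with a warning).
#' @param config A `disambiguation_config`.
#' @param tables Symbol tables.
#' @return `mentions` with scores and selection flags filled in.
#' @export
disambiguate <- function(mentions, article_text, docs,
                         config = disambiguation_config(),
                         tables = symbol_tables()) {
  stopifnot("candidates" %in% names(mentions))
  article <- document_tokens(article_text, tables)
  missing_ids <- character(0)
  mentions$candidates <- lapply(mentions$candidates, function(cand) {
    k <- nrow(cand)
    if (!k) return(cand)
    if (k == 1L) {
      cand$score <- 0
      cand$selected <- TRUE
      return(cand)
    }
    cand$score <- vapply(cand$gene_id, function(id) {
      doc <- docs[[id]]
      if (is.null(doc)) {
        missing_ids <<- c(missing_ids, id)
        return(0)
      }
      score_candidate(article, doc, config$method)
    }, numeric(1))
    sel <- select_candidates(cand$score, config$mode)
    cand$selected <- sel$selected
    ord <- order(-cand$score, cand$gene_id, method = "radix")
    cand <- cand[ord, , drop = FALSE]
    rownames(cand) <- NULL
    cand
  })
  if (length(missing_ids)) {
    warning("no gene-document for gene id(s): ",
            paste(unique(missing_ids), collapse = ", "),
            "; scored 0")
  }
  mentions
}

#' Full normalization of tagged mentions
#'
#' Attaches dictionary candidates to each mention (flexible or machine
#' learning matching) and disambiguates them against the article text.
#' When no gene-document store is supplied, documents are built from the
#' dictionary records alone (symbols and synonyms).
#'
#' @param mentions Mention data.frame from [tag()] (columns `text`,
#'   `start`, `end`).
#' @param article_text The text the mentions were extracted from.
#' @param store A `dictionary_store`.
#' @param tables Symbol tables.
#' @param matching `"flexible"` or `"ml"`.
#' @param model A `matcher_model`, required when `matching = "ml"`.
#' @param docs Optional gene-document store from
#'   [load_gene_documents()].
#' @param config A `disambiguation_config`.
#' @return The mention data.frame with a `candidates` list column, scored
#'   and selection-flagged.
#' @export
normalize_mentions <- function(mentions, article_text, store, tables,
                               matching = c("flexible", "ml"),
                               model = NULL, docs = NULL,
                               config = disambiguation_config()) {
  matching <- match.arg(matching)
  if (matching == "ml" && is.null(model)) {
    stop("machine learning matching requires a trained matcher_model")
  }
  mentions$candidates <- lapply(mentions$text, function(txt) {
    if (matching == "flexible") {
      flexible_match(txt, store, tables)
    } else {
      ml_match(txt, store, model, tables)
    }
  })
  if (is.null(docs)) {
    docs <- lapply(seq_len(nrow(store$records)), function(i) {
      build_gene_document(store$records[i, , drop = FALSE], NULL, tables)
    })
    names(docs) <- store$records$gene_id
  }
  disambiguate(mentions, article_text, docs, config, tables)
}

#' Flatten normalized mentions to a result table
#'
#' One row per (mention, candidate), in the column layout of the
#' normalization output: mention offsets and text, the matched gene id
#' and synonym, the disambiguation score and the selection flag.
#'
#' @param mentions Normalized mention data.frame with a `candidates`
#'   list column.
#' @param sentence_id Optional sentence identifier recycled across rows.
#' @return A data.frame; mentions without candidates yield one row with
#'   `NA` in the candidate columns.
#' @export
normalization_table <- function(mentions, sentence_id = NA_character_) {
  rows <- lapply(seq_len(nrow(mentions)), function(i) {
    cand <- mentions$candidates[[i]]
    if (is.null(cand) || !nrow(cand)) {
      cand <- data.frame(gene_id = NA_character_,
                         matched_synonym = NA_character_,
                         score = NA_real_, selected = NA,
                         stringsAsFactors = FALSE)
    }
    data.frame(sentence_id = sentence_id,
               start = mentions$start[i], end = mentions$end[i],
               mention = mentions$text[i], cand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
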