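# Case-based-reasoning tagger. Training turns every token of every
# annotated sentence into one known case (the verbatim token) and one
# unknown case per shape variant, each carrying the token's category (gene
# mention or not), the category of the preceding token (false at sentence
# start) and a frequency counting repetitions. Tagging retrieves cases in
# the order known -> shape variants -> sub-parts, highest frequency wins,
# ties fall to the negative class.

KEY_SEP <- "\x1f"

case_key <- function(a, b, c = NULL) {
  if (is.null(c)) paste(a, b, sep = KEY_SEP) else paste(a, b, c, sep = KEY_SEP)
}

new_case_base <- function(known, unknown, model_id) {
  known <- known[order(known$token_text, known$category, known$prev_category,
                       method = "radix"), , drop = FALSE]
  unknown <- unknown[order(unknown$shape, unknown$category,
                           unknown$prev_category, method = "radix"), ,
                     drop = FALSE]
  rownames(known) <- NULL
  rownames(unknown) <- NULL
  structure(list(known = known, unknown = unknown, model_id = model_id),
            class = "case_base")
}

empty_cases <- function(key_col) {
  df <- data.frame(x = character(), category = logical(),
                   prev_category = logical(), frequency = integer(),
                   stringsAsFactors = FALSE)
  names(df)[1] <- key_col
  df
}

#' @export
print.case_base <- function(x, ...) {
  cat(sprintf("case_base '%s': %d known cases, %d unknown cases\n",
              x$model_id, nrow(x$known), nrow(x$unknown)))
  invisible(x)
}

env_to_cases <- function(env, key_col) {
  keys <- ls(env, sorted = FALSE)
  if (!length(keys)) return(empty_cases(key_col))
  parts <- strsplit(keys, KEY_SEP, fixed = TRUE)
  df <- data.frame(
    x = vapply(parts, `[[`, "", 1L),
    category = vapply(parts, `[[`, "", 2L) == "TRUE",
    prev_category = vapply(parts, `[[`, "", 3L) == "TRUE",
    frequency = vapply(keys, function(k) env[[k]], 1L, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  names(df)[1] <- key_col
  df
}

upsert <- function(env, key, by = 1L) {
  cur <- env[[key]]
  env[[key]] <- if (is.null(cur)) by else cur + by
}

#' Train a case base from an annotated corpus
#'
#' For every token of every sentence one known case and one unknown case
#' per shape variant are recorded; a token's category is true when it
#' overlaps a gold mention (every token covered by a multi-token mention
#' counts), and the preceding category is the gold category of the token
#' before it (false at sentence start). Repetitions of a case increment
#' its frequency.
#'
#' @param sentences Sentence data.frame from [read_sentences()].
#' @param annotations Annotation data.frame from [read_annotations()];
#'   every `sentence_id` must exist in `sentences`.
#' @param tables Symbol tables from [symbol_tables()].
#' @param model_id Short identifier used to name the on-disk store.
#' @return An object of class `case_base`.
#' @export
train_tagger <- function(sentences, annotations, tables, model_id = "model") {
  stopifnot(nzchar(model_id))
  dangling <- setdiff(annotations$sentence_id, sentences$sentence_id)
  if (length(dangling)) {
    stop(sprintf("annotations reference unknown sentence id '%s'", dangling[1]))
  }
  if (!nrow(sentences)) {
    warning("empty corpus: trained case base has no cases")
    return(new_case_base(empty_cases("token_text"), empty_cases("shape"),
                         model_id))
  }
  known_env <- new.env(parent = emptyenv())
  unknown_env <- new.env(parent = emptyenv())
  ann_by_id <- split(annotations, annotations$sentence_id)
  for (i in seq_len(nrow(sentences))) {
    spans <- token_spans(sentences$text[i])
    if (!nrow(spans)) next
    ann <- ann_by_id[[sentences$sentence_id[i]]]
    cat_vec <- token_categories(spans, ann)
    prev <- c(FALSE, cat_vec[-length(cat_vec)])
    for (j in seq_len(nrow(spans))) {
      upsert(known_env, case_key(spans$text[j], cat_vec[j], prev[j]))
      for (sh in shape_variants(spans$text[j], tables)) {
        upsert(unknown_env, case_key(sh, cat_vec[j], prev[j]))
      }
    }
  }
  new_case_base(env_to_cases(known_env, "token_text"),
                env_to_cases(unknown_env, "shape"), model_id)
}

# A token is a gene token when its non-space span overlaps any gold span.
token_categories <- function(spans, ann) {
  if (is.null(ann) || !nrow(ann)) return(rep(FALSE, nrow(spans)))
  vapply(seq_len(nrow(spans)), function(j) {
    any(spans$ns_start[j] <= ann$end & spans$ns_end[j] >= ann$start)
  }, logical(1))
}

#' Merge two case bases
#'
#' Union of cases; frequencies of identical (attribute, category,
#' preceding category) triples are summed. Commutative up to ordering.
#'
#' @param base_a,base_b Case bases.
#' @param model_id Identifier of the merged base (defaults to
#'   `base_a$model_id`).
#' @return A `case_base`.
#' @export
merge_cases <- function(base_a, base_b, model_id = base_a$model_id) {
  merge_one <- function(a, b, key_col) {
    all <- rbind(a, b)
    if (!nrow(all)) return(a)
    key <- case_key(all[[key_col]], all$category, all$prev_category)
    freq <- tapply(all$frequency, key, sum)
    first <- !duplicated(key)
    out <- all[first, , drop = FALSE]
    out$frequency <- as.integer(freq[key[first]])
    out
  }
  new_case_base(merge_one(base_a$known, base_b$known, "token_text"),
                merge_one(base_a$unknown, base_b$unknown, "shape"),
                model_id)
}

# Retrieval index: for each (attribute, prev) pair the summed positive and
# negative frequencies.
case_index <- function(base) {
  build <- function(df, key_col) {
    env <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(df))) {
      k <- case_key(df[[key_col]][i], df$prev_category[i])
      cur <- env[[k]]
      if (is.null(cur)) cur <- c(pos = 0L, neg = 0L)
      slot <- if (df$category[i]) "pos" else "neg"
      cur[slot] <- cur[slot] + df$frequency[i]
      env[[k]] <- cur
    }
    env
  }
  list(known = build(base$known, "token_text"),
       unknown = build(base$unknown, "shape"))
}

# Highest frequency wins; a tie goes to the negative class.
decide <- function(hit) unname(hit["pos"] > hit["neg"])

# Sub-parts of a token: split on punctuation and at letter/digit
# boundaries. Used as the third retrieval level.
sub_parts <- function(token_text) {
  x <- gsub("[^[:alnum:]]+", " ", token_text)
  x <- gsub("([[:alpha:]])([[:digit:]])", "\\1 \\2", x)
  x <- gsub("([[:digit:]])([[:alpha:]])", "\\1 \\2", x)
  parts <- strsplit(trimws(x), " +")[[1]]
  parts[nzchar(parts)]
}

#' Classify one token with a case base
#'
#' Retrieval order: (1) known cases matching the verbatim token and the
#' preceding category; (2) unknown cases matching a shape variant (plain
#' shape first, then prefix form, then suffix form); (3) sub-parts of the
#' token, positive when any part retrieves a positive case with frequency
#' strictly greater than its negative retrieval; (4) default negative.
#'
#' @param token_text Non-empty token string.
#' @param prev_category Category assigned to the preceding token.
#' @param base A `case_base`.
#' @param tables Symbol tables.
#' @param index Optional prebuilt retrieval index (internal use).
#' @return Logical: is the token part of a gene/protein mention.
#' @export
classify_token <- function(token_text, prev_category, base, tables,
                           index = NULL) {
  if (is.null(index)) index <- case_index(base)
  retrieve <- function(tok) {
    hit <- index$known[[case_key(tok, prev_category)]]
    if (!is.null(hit)) return(hit)
    for (sh in shape_variants(tok, tables)) {
      hit <- index$unknown[[case_key(sh, prev_category)]]
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  hit <- index$known[[case_key(token_text, prev_category)]]
  if (!is.null(hit)) return(decide(hit))
  for (sh in shape_variants(token_text, tables)) {
    hit <- index$unknown[[case_key(sh, prev_category)]]
    if (!is.null(hit)) return(decide(hit))
  }
  parts <- sub_parts(token_text)
  if (length(parts) > 1L) {
    for (p in parts) {
      hit <- retrieve(p)
      if (!is.null(hit) && decide(hit)) return(TRUE)
    }
  }
  FALSE
}

#' Tag free text with gene/protein mentions
#'
#' A forward pass assigns categories left to right using the running
#' preceding category, then a backward pass re-assigns them right to left
#' (a token's context being the backward category of the token to its
#' right); a token is positive when either pass marks it. Maximal runs of
#' positive tokens become one mention with offsets in the corpus
#' convention.
#'
#' @param text Input text (treated as one sentence; no sentence
#'   splitting is performed).
#' @param base A trained `case_base`.
#' @param tables Symbol tables.
#' @return A data.frame with columns `text`, `start`, `end` (space
#'   ignoring, inclusive), one row per mention.
#' @export
tag <- function(text, base, tables) {
  empty <- data.frame(text = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  spans <- token_spans(text)
  n <- nrow(spans)
  if (!n) return(empty)
  index <- case_index(base)
  fwd <- logical(n)
  prev <- FALSE
  for (i in seq_len(n)) {
    fwd[i] <- classify_token(spans$text[i], prev, base, tables, index)
    prev <- fwd[i]
  }
  bwd <- logical(n)
  nxt <- FALSE
  for (i in rev(seq_len(n))) {
    bwd[i] <- classify_token(spans$text[i], nxt, base, tables, index)
    nxt <- bwd[i]
  }
  pos <- fwd | bwd
  if (!any(pos)) return(empty)
  r <- rle(pos)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  runs <- which(r$values)
  data.frame(
    text = substring(text, spans$char_start[starts[runs]],
                     spans$char_end[stops[runs]]),
    start = spans$ns_start[starts[runs]],
    end = spans$ns_end[stops[runs]],
    stringsAsFactors = FALSE
  )
}

#' Tag every sentence of a corpus
#'
#' @param sentences Sentence data.frame from [read_sentences()].
#' @param base A trained `case_base`.
#' @param tables Symbol tables.
#' @return An annotation data.frame (`sentence_id`, `start`, `end`,
#'   `text`) suitable for [write_annotations()].
#' @export
tag_corpus <- function(sentences, base, tables) {
  out <- lapply(seq_len(nrow(sentences)), function(i) {
    m <- tag(sentences$text[i], base, tables)
    if (!nrow(m)) return(NULL)
    cbind(data.frame(sentence_id = sentences$sentence_id[i],
                     stringsAsFactors = FALSE), m)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sentence_id = character(), start = integer(),
                      end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  }
  out[, c("sentence_id", "start", "end", "text")]
}

#' Save a case base as TAB-separated text
#'
#' Writes `known.tsv` and `unknown.tsv` (one case per line) under
#' `<dir>/<model_id>/`.
#'
#' @param base A `case_base`.
#' @param dir Parent directory of the store.
#' @return The store directory, invisibly.
#' @export
save_case_base <- function(base, dir) {
  store <- file.path(dir, base$model_id)
  dir.create(store, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(base$known, file.path(store, "known.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(base$unknown, file.path(store, "unknown.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(store)
}

#' Load a case base saved by [save_case_base()]
#'
#' @param dir Parent directory of the store.
#' @param model_id Identifier the base was saved under.
#' @return A `case_base`.
#' @export
load_case_base <- function(dir, model_id) {
  store <- file.path(dir, model_id)
  read_one <- function(name, key_col) {
    df <- utils::read.table(file.path(store, name), sep = "\t", header = TRUE,
                            colClasses = c("character", "logical", "logical",
                                           "integer"),
                            quote = "", comment.char = "")
    names(df)[1] <- key_col
    df
  }
  new_case_base(read_one("known.tsv", "token_text"),
                read_one("unknown.tsv", "shape"), model_id)
}
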