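# Normalized string similarity metrics for the trainable matcher. All are
# computed on lowercased input and normalized to [0, 1]:
#   levenshtein   1 - d / max(len)            (distance via utils::adist)
#   jaro_winkler  native [0, 1], prefix scale 0.1 over at most 4 characters
#   smith_waterman local alignment (match 2, mismatch -1, gap -1) / (2 min(len))
#   monge_elkan   mean over tokens of the best Jaro-Winkler partner,
#                 averaged over both directions
#   soft_tfidf    TF-IDF-weighted soft token overlap with Jaro-Winkler
#                 partner threshold 0.9, averaged over both directions;
#                 IDF from an optional corpus, else uniform weights

jaro_sim <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca)
  lb <- length(cb)
  if (la == 0L || lb == 0L) return(0)
  window <- max(0L, max(la, lb) %/% 2L - 1L)
  matched_b <- logical(lb)
  match_a <- integer(0)
  for (i in seq_len(la)) {
    lo <- max(1L, i - window)
    hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!matched_b[j] && ca[i] == cb[j]) {
        matched_b[j] <- TRUE
        match_a <- c(match_a, i)
        break
      }
    }
  }
  m <- length(match_a)
  if (m == 0L) return(0)
  sa <- ca[match_a]
  sb <- cb[matched_b]
  t <- sum(sa != sb) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

jaro_winkler_sim <- function(a, b, p = 0.1, max_prefix = 4L) {
  j <- jaro_sim(a, b)
  l <- 0L
  n <- min(nchar(a), nchar(b), max_prefix)
  while (l < n && substr(a, l + 1L, l + 1L) == substr(b, l + 1L, l + 1L)) {
    l <- l + 1L
  }
  j + l * p * (1 - j)
}

smith_waterman_sim <- function(a, b, match = 2, mismatch = -1, gap = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca)
  lb <- length(cb)
  best <- 0
  prev <- numeric(lb + 1L)
  for (i in seq_len(la)) {
    cur <- numeric(lb + 1L)
    for (j in seq_len(lb)) {
      s <- prev[j] + if (ca[i] == cb[j]) match else mismatch
      cur[j + 1L] <- max(0, s, prev[j + 1L] + gap, cur[j] + gap)
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best / (match * min(la, lb))
}

ws_tokens <- function(x) {
  t <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  t[nzchar(t)]
}

monge_elkan_sim <- function(a, b) {
  one_way <- function(ta, tb) {
    mean(vapply(ta, function(t) {
      max(vapply(tb, function(u) jaro_winkler_sim(t, u), numeric(1)))
    }, numeric(1)))
  }
  ta <- ws_tokens(a)
  tb <- ws_tokens(b)
  (one_way(ta, tb) + one_way(tb, ta)) / 2
}

soft_tfidf_sim <- function(a, b, corpus = NULL, theta = 0.9) {
  idf <- function(tok) {
    if (is.null(corpus)) return(1)
    n_docs <- length(corpus)
    df <- sum(vapply(corpus, function(d) tok %in% d, logical(1)))
    log((n_docs + 1) / (df + 1)) + 1
  }
  weights <- function(toks) {
    tf <- table(toks)
    w <- as.numeric(tf[toks]) * vapply(toks, idf, numeric(1))
    w / sqrt(sum((as.numeric(tf) * vapply(names(tf), idf, numeric(1)))^2))
  }
  one_way <- function(ta, tb) {
    wa <- weights(ta)
    wb <- weights(tb)
    s <- 0
    for (i in seq_along(ta)) {
      sims <- vapply(tb, function(u) jaro_winkler_sim(ta[i], u), numeric(1))
      j <- which.max(sims)
      if (sims[j] >= theta) s <- s + wa[i] * wb[j] * sims[j]
    }
    min(1, s)
  }
  ta <- ws_tokens(a)
  tb <- ws_tokens(b)
  (one_way(ta, tb) + one_way(tb, ta)) / 2
}

#' Normalized string similarity
#'
#' Five metrics, each mapped to \[0, 1\] with 1 for identical strings.
#' Input is lowercased before comparison. For `soft_tfidf` an optional
#' corpus (a list of token vectors, or a character vector of strings that
#' are tokenized on whitespace) supplies the IDF statistics; without it,
#' token weights are uniform.
#'
#' @param a,b Non-empty strings.
#' @param metric One of `levenshtein`, `jaro_winkler`, `smith_waterman`
#'   (the matcher's default), `monge_elkan`, `soft_tfidf`.
#' @param corpus Optional corpus for `soft_tfidf`.
#' @return Similarity in \[0, 1\].
#' @examples
#' string_similarity("abc", "abd", "levenshtein")  # 1 - 1/3
#' @export
string_similarity <- function(a, b,
                              metric = c("levenshtein", "jaro_winkler",
                                         "smith_waterman", "monge_elkan",
                                         "soft_tfidf"),
                              corpus = NULL) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L,
            length(b) == 1L, nzchar(a), nzchar(b))
  metric <- match.arg(metric)
  a <- tolower(a)
  b <- tolower(b)
  if (!is.null(corpus) && is.character(corpus)) {
    corpus <- lapply(tolower(corpus), ws_tokens)
  }
  switch(metric,
    levenshtein = 1 - drop(utils::adist(a, b)) / max(nchar(a), nchar(b)),
    jaro_winkler = jaro_winkler_sim(a, b),
    smith_waterman = smith_waterman_sim(a, b),
    monge_elkan = monge_elkan_sim(a, b),
    soft_tfidf = soft_tfidf_sim(a, b, corpus)
  )
}
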