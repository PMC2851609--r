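# Tokenization, token shapes and n-gram similarity: the primitives every
# other stage (tagger cases, synonym variations, matcher features) is built
# on. Tokens partition the non-space characters of the input, so offsets in
# the corpus convention (0-based, inclusive, spaces ignored) can be derived
# from token lengths alone.

is_punct_char <- function(ch) !grepl("[[:alnum:]]", ch)

.bracket_open <- c(")" = "(", "]" = "[", "}" = "{")

# Split one whitespace-delimited chunk into tokens: peel leading punctuation
# characters one by one, then trailing ones, but keep a trailing closing
# bracket whose opener sits inside the core (so "cGKI(alpha)" stays whole).
# Returns relative 1-based (start, end) pairs covering the chunk.
split_chunk <- function(txt) {
  n <- nchar(txt)
  s <- 1L
  e <- n
  lead <- integer(0)
  while (e > s && is_punct_char(substr(txt, s, s))) {
    lead <- c(lead, s)
    s <- s + 1L
  }
  trail <- integer(0)
  while (e > s) {
    ch <- substr(txt, e, e)
    if (!is_punct_char(ch)) break
    if (ch %in% names(.bracket_open) &&
        grepl(.bracket_open[[ch]], substr(txt, s, e - 1L), fixed = TRUE)) {
      break
    }
    trail <- c(e, trail)
    e <- e - 1L
  }
  starts <- c(lead, s, trail)
  ends <- c(lead, e, trail)
  data.frame(start = starts, end = ends)
}

#' Tokenize a sentence
#'
#' Splits on whitespace, then peels leading and trailing punctuation
#' characters into their own tokens; internal punctuation (hyphens,
#' balanced parentheses) stays inside the token. Concatenating the token
#' texts in order reproduces the sentence's non-space characters exactly.
#'
#' @param sentence A string; may be empty.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("SGPT, SGOT, and alkaline phosphatase")
#' @export
tokenize <- function(sentence) {
  token_spans(sentence)$text
}

#' Tokenize with character and corpus offsets
#'
#' Like [tokenize()] but returns, for every token, its 1-based character
#' span in the original string and its 0-based inclusive span in the
#' space-ignoring corpus offset convention.
#'
#' @param sentence A string.
#' @return A data.frame with columns `text`, `index` (0-based token
#'   position), `char_start`, `char_end`, `ns_start`, `ns_end`.
#' @export
token_spans <- function(sentence) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  empty <- data.frame(text = character(), index = integer(),
                      char_start = integer(), char_end = integer(),
                      ns_start = integer(), ns_end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(sentence) || !nzchar(sentence)) return(empty)
  m <- gregexpr("\\S+", sentence)[[1]]
  if (m[1] == -1L) return(empty)
  chunk_start <- as.integer(m)
  chunk_len <- attr(m, "match.length")
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_along(chunk_start)) {
    chunk <- substr(sentence, chunk_start[i], chunk_start[i] + chunk_len[i] - 1L)
    rel <- split_chunk(chunk)
    starts <- c(starts, chunk_start[i] + rel$start - 1L)
    ends <- c(ends, chunk_start[i] + rel$end - 1L)
  }
  texts <- substring(sentence, starts, ends)
  lens <- nchar(texts)
  ns_end <- cumsum(lens) - 1L
  ns_start <- ns_end - lens + 1L
  data.frame(text = texts, index = seq_along(texts) - 1L,
             char_start = starts, char_end = ends,
             ns_start = ns_start, ns_end = ns_end,
             stringsAsFactors = FALSE)
}

# Character-class shape of a string: uppercase letters repeat as 'A' (one
# per letter), lowercase and digit runs collapse to single 'a'/'1', Greek
# names (whole case-homogeneous subrun, case-insensitive) become 'g',
# punctuation characters are kept literally.
char_class_shape <- function(x, greek) {
  chars <- strsplit(x, "", fixed = FALSE)[[1]]
  cls <- ifelse(grepl("[[:upper:]]", chars), "U",
         ifelse(grepl("[[:lower:]]", chars), "l",
         ifelse(grepl("[[:digit:]]", chars), "d", "p")))
  r <- rle(cls)
  pos <- cumsum(c(1L, r$lengths))
  out <- character(length(r$values))
  for (i in seq_along(r$values)) {
    run <- substr(x, pos[i], pos[i + 1L] - 1L)
    out[i] <- switch(r$values[i],
      U = if (tolower(run) %in% greek) "g" else
            strrep("A", r$lengths[i]),
      l = if (run %in% greek) "g" else "a",
      d = "1",
      p = run)
  }
  paste0(out, collapse = "")
}

#' Shape encoding of a token
#'
#' Encodes a token as a string over the shape alphabet: `A` per uppercase
#' letter, a single `a` per lowercase run, a single `1` per digit run, `g`
#' for a spelled-out Greek letter, `p` for a whole-token stopword, and
#' punctuation characters kept literally. Tokens consisting of five or more
#' lowercase letters additionally receive a prefix form (literal 3-letter
#' prefix, then `$`, then the shape of the remainder) and a suffix form
#' (shape, `$`, literal 4-letter suffix).
#'
#' @param token_text Non-empty token string without whitespace.
#' @param tables Symbol tables from [symbol_tables()].
#' @return A list of class `shape_set` with elements `plain`,
#'   `prefix_form` and `suffix_form` (the latter two `NA` when not
#'   applicable).
#' @examples
#' tabs <- symbol_tables()
#' shape_of("Bmp4", tabs)$plain        # "Aa1"
#' shape_of("patterning", tabs)$prefix_form  # "pat$a"
#' @export
shape_of <- function(token_text, tables) {
  stopifnot(is.character(token_text), length(token_text) == 1L)
  if (is.na(token_text) || !nzchar(token_text) ||
      grepl("[[:space:]]", token_text)) {
    stop("shape_of() requires a non-empty token without whitespace")
  }
  greek <- tables$greek_letters
  plain <- if (tolower(token_text) %in% tables$stopwords) "p"
           else char_class_shape(token_text, greek)
  prefix_form <- suffix_form <- NA_character_
  if (!plain %in% c("p", "g") && grepl("^[[:lower:]]{5,}$", token_text)) {
    n <- nchar(token_text)
    prefix_form <- paste0(substr(token_text, 1L, 3L), "$",
                          char_class_shape(substr(token_text, 4L, n), greek))
    suffix_form <- paste0(char_class_shape(substr(token_text, 1L, n - 4L), greek),
                          "$", substr(token_text, n - 3L, n))
  }
  structure(list(plain = plain, prefix_form = prefix_form,
                 suffix_form = suffix_form),
            class = "shape_set")
}

#' @export
print.shape_set <- function(x, ...) {
  cat("shape:", x$plain)
  if (!is.na(x$prefix_form)) cat(" |", x$prefix_form)
  if (!is.na(x$suffix_form)) cat(" |", x$suffix_form)
  cat("\n")
  invisible(x)
}

# All defined shape variants of a token, most specific first.
shape_variants <- function(token_text, tables) {
  s <- shape_of(token_text, tables)
  v <- c(s$plain, s$prefix_form, s$suffix_form)
  v[!is.na(v)]
}

#' Character n-grams of a string
#'
#' All contiguous length-`n` substrings of the lowercased text, as a
#' multiset (duplicates kept).
#'
#' @param text A string.
#' @param n Gram length, at least 1.
#' @return Character vector of n-grams; empty when the text is shorter
#'   than `n`.
#' @export
ngrams <- function(text, n) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a single integer >= 1")
  }
  n <- as.integer(n)
  x <- tolower(text)
  len <- nchar(x)
  if (len < n) return(character(0))
  substring(x, 1L:(len - n + 1L), n:len)
}

# Dice coefficient over two gram multisets given as table() objects.
dice_tables <- function(ta, tb) {
  la <- sum(ta)
  lb <- sum(tb)
  if (la + lb == 0L) return(0)
  shared <- intersect(names(ta), names(tb))
  if (!length(shared)) return(0)
  inter <- sum(pmin(ta[shared], tb[shared]))
  2 * inter / (la + lb)
}

#' N-gram similarity of two strings
#'
#' Dice coefficient `2|G(a) n G(b)| / (|G(a)| + |G(b)|)` over the multiset
#' intersection of lowercased character n-grams. Symmetric; 1 for
#' identical strings; defined as 0 when both strings are shorter than `n`.
#'
#' @param a,b Non-empty strings.
#' @param n Gram length.
#' @return A fraction in \[0, 1\].
#' @examples
#' ngram_similarity("abc", "abd", 2)  # 0.5
#' @export
ngram_similarity <- function(a, b, n) {
  stopifnot(nzchar(a), nzchar(b))
  dice_tables(table(ngrams(a, n)), table(ngrams(b, n)))
}
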