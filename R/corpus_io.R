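# BioCreative 2 Gene Mention corpus dialect: a sentence file with lines
# "<id> <text>" and an annotation file with lines "<id>|<start> <end>|<text>"
# where start/end are 0-based, inclusive, and count only non-space
# characters of the sentence.

read_source_lines <- function(file = NULL, text = NULL) {
  if (!is.null(text)) {
    if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
      text <- strsplit(text, "\r?\n")[[1]]
    }
    return(text)
  }
  readLines(file, encoding = "UTF-8", warn = FALSE)
}

nonspace_length <- function(x) nchar(gsub(" ", "", x, fixed = TRUE))

#' Read a BC2-GM sentence file
#'
#' Each non-empty line is `<id><space><sentence text>`; the id is the
#' first whitespace-delimited field and the text is the remainder
#' (internal spaces kept).
#'
#' @param file Path to the sentence file.
#' @param text Alternatively, the file content as a character vector of
#'   lines or one newline-separated string.
#' @return A data.frame with columns `sentence_id` and `text`.
#' @export
read_sentences <- function(file = NULL, text = NULL) {
  lines <- read_source_lines(file, text)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(data.frame(sentence_id = character(), text = character(),
                      stringsAsFactors = FALSE))
  }
  sep <- regexpr(" ", lines, fixed = TRUE)
  bad <- which(sep < 0L)
  if (length(bad)) {
    stop(sprintf("sentence file line %d: no space separator between id and text",
                 lineno[bad[1]]))
  }
  ids <- substr(lines, 1L, sep - 1L)
  data.frame(sentence_id = ids,
             text = substr(lines, sep + 1L, nchar(lines)),
             stringsAsFactors = FALSE)
}

#' Read a BC2-GM annotation file
#'
#' Each line is `<id>|<start> <end>|<mention text>` with offsets in the
#' space-ignoring convention. The length invariant
#' `end - start + 1 == `non-space length of the mention is verified, and
#' overlapping mentions within one sentence are rejected.
#'
#' @inheritParams read_sentences
#' @return A data.frame with columns `sentence_id`, `start`, `end`,
#'   `text`.
#' @export
read_annotations <- function(file = NULL, text = NULL) {
  lines <- read_source_lines(file, text)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  empty <- data.frame(sentence_id = character(), start = integer(),
                      end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  pat <- "^([^|]+)\\|([0-9]+) ([0-9]+)\\|(.*)$"
  ok <- grepl(pat, lines)
  if (any(!ok)) {
    stop(sprintf("annotation file line %d: expected '<id>|<start> <end>|<mention>'",
                 lineno[which(!ok)[1]]))
  }
  ann <- data.frame(
    sentence_id = sub(pat, "\\1", lines),
    start = as.integer(sub(pat, "\\2", lines)),
    end = as.integer(sub(pat, "\\3", lines)),
    text = sub(pat, "\\4", lines),
    stringsAsFactors = FALSE
  )
  bad_len <- which(ann$end - ann$start + 1L != nonspace_length(ann$text) |
                   ann$start > ann$end)
  if (length(bad_len)) {
    stop(sprintf(
      "annotation file line %d: offsets (%d, %d) do not match the non-space length of '%s'",
      lineno[bad_len[1]], ann$start[bad_len[1]], ann$end[bad_len[1]],
      ann$text[bad_len[1]]))
  }
  for (id in unique(ann$sentence_id)) {
    a <- ann[ann$sentence_id == id, ]
    a <- a[order(a$start, a$end), ]
    if (nrow(a) > 1L && any(a$start[-1L] <= a$end[-nrow(a)])) {
      stop(sprintf("annotation file: overlapping mentions in sentence %s", id))
    }
  }
  ann
}

#' Space-ignoring offsets of a mention within a sentence
#'
#' Computes the corpus-convention offsets of the `occurrence`-th substring
#' occurrence of `mention_text` in `sentence_text`: `start` is the number
#' of non-space characters strictly before the occurrence, `end` is
#' `start` plus the non-space length of the mention minus one.
#'
#' @param sentence_text The sentence string.
#' @param mention_text The mention string as it appears in the sentence.
#' @param occurrence 0-based occurrence index (default first).
#' @return Integer vector `c(start, end)`.
#' @examples
#' s <- "SGPT, SGOT, and alkaline phosphatase concentrations"
#' mention_offsets(s, "alkaline phosphatase")  # c(13, 31)
#' @export
mention_offsets <- function(sentence_text, mention_text, occurrence = 0L) {
  stopifnot(nzchar(mention_text))
  m <- gregexpr(mention_text, sentence_text, fixed = TRUE)[[1]]
  if (m[1] == -1L || length(m) < occurrence + 1L) {
    stop(sprintf("mention '%s' (occurrence %d) not found in sentence",
                 mention_text, occurrence))
  }
  pos <- m[occurrence + 1L]
  before <- substr(sentence_text, 1L, pos - 1L)
  start <- nonspace_length(before)
  end <- start + nonspace_length(mention_text) - 1L
  c(start = start, end = end)
}

#' Write annotations in the BC2-GM dialect
#'
#' Inverse of [read_annotations()]: the round trip is bit-exact.
#'
#' @param annotations A data.frame with columns `sentence_id`, `start`,
#'   `end`, `text`.
#' @param file Optional path; when `NULL` the formatted text is returned.
#' @return The annotation text, invisibly when written to a file. An empty
#'   annotation set yields `""`.
#' @export
write_annotations <- function(annotations, file = NULL) {
  stopifnot(all(c("sentence_id", "start", "end", "text") %in% names(annotations)))
  if (nrow(annotations)) {
    bad <- which(annotations$end - annotations$start + 1L !=
                 nonspace_length(annotations$text))
    if (length(bad)) {
      stop(sprintf("annotation %d violates the offset length invariant", bad[1]))
    }
  }
  lines <- sprintf("%s|%d %d|%s", annotations$sentence_id,
                   annotations$start, annotations$end, annotations$text)
  out <- if (length(lines)) paste0(paste(lines, collapse = "\n"), "\n") else ""
  if (is.null(file)) return(out)
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(out), con)
  invisible(out)
}

#' Convert corpus offsets to ordinary half-open character offsets
#'
#' Maps an annotation's space-ignoring inclusive offsets back to 0-based
#' half-open character offsets in the original sentence string, for
#' interoperability with standoff formats that count spaces.
#'
#' @param annotation One row of an annotation data.frame.
#' @param sentence_text The sentence the annotation refers to.
#' @return Integer vector `c(start, end)` with `end` exclusive.
#' @export
char_offsets <- function(annotation, sentence_text) {
  chars <- strsplit(sentence_text, "", fixed = TRUE)[[1]]
  ns_index <- cumsum(chars != " ") - 1L
  ns_index[chars == " "] <- NA_integer_
  first <- which(ns_index == annotation$start)
  last <- which(ns_index == annotation$end)
  if (!length(first) || !length(last)) {
    stop("annotation offsets fall outside the sentence")
  }
  c(start = first[1] - 1L, end = last[1])
}
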