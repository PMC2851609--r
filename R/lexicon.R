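# Organism dictionary: gene records from Entrez gene_info-style TSV,
# normalized synonym variations produced by a tiered editing cascade, and
# flexible matching (exact matching on variations of both the mention and
# the synonyms).

#' Load gene records from a gene_info-style TSV
#'
#' Entrez dialect: TAB-separated, column 1 `tax_id`, column 2 `GeneID`,
#' column 3 `Symbol`, column 5 pipe-separated `Synonyms`, `-` meaning
#' empty. Rows whose `tax_id` differs from `taxon_id` are skipped; the
#' symbol is always included among the synonyms.
#'
#' @param file Path to the TSV (lines starting with `#` are skipped).
#' @param taxon_id NCBI taxonomy id to keep, as a string.
#' @param text Alternatively the file content as lines or one string.
#' @return A data.frame with columns `gene_id`, `taxon_id`, `symbol` and a
#'   list column `synonyms`.
#' @export
load_gene_info <- function(file = NULL, taxon_id, text = NULL) {
  lines <- read_source_lines(file, text)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 5L)
  if (length(short)) {
    stop(sprintf("gene_info row %d: fewer than 5 TAB-separated columns",
                 lineno[short[1]]))
  }
  tax <- vapply(fields, `[[`, "", 1L)
  fields <- fields[tax == taxon_id]
  if (!length(fields)) {
    warning(sprintf("no gene_info rows for taxon %s", taxon_id))
    return(data.frame(gene_id = character(), taxon_id = character(),
                      symbol = character(),
                      synonyms = I(list()), stringsAsFactors = FALSE))
  }
  gene_id <- vapply(fields, `[[`, "", 2L)
  if (anyDuplicated(gene_id)) {
    stop(sprintf("duplicated gene id '%s' in gene_info",
                 gene_id[duplicated(gene_id)][1]))
  }
  symbol <- vapply(fields, `[[`, "", 3L)
  syn_raw <- vapply(fields, `[[`, "", 5L)
  synonyms <- lapply(seq_along(fields), function(i) {
    syns <- if (identical(syn_raw[i], "-")) character(0) else
      strsplit(syn_raw[i], "|", fixed = TRUE)[[1]]
    unique(c(symbol[i], syns[nzchar(syns)]))
  })
  data.frame(gene_id = gene_id, taxon_id = taxon_id, symbol = symbol,
             synonyms = I(synonyms), stringsAsFactors = FALSE)
}

# Split a text into parenthesis parts: the outside with parenthetical
# material removed, plus each parenthetical content as its own part.
paren_parts <- function(text) {
  insides <- character(0)
  x <- text
  while (grepl("\\(([^()]*)\\)", x)) {
    m <- regmatches(x, gregexpr("\\(([^()]*)\\)", x))[[1]]
    insides <- c(insides, substr(m, 2L, nchar(m) - 1L))
    x <- gsub("\\(([^()]*)\\)", " ", x)
  }
  parts <- c(x, insides)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

# Split a letters-only word at a leading or trailing Greek name, but only
# when the split point is a case-class boundary (so "beta" is not cut at
# its embedded "eta"). Recurses into the remainder.
split_greek_word <- function(word, greek) {
  n <- nchar(word)
  lw <- tolower(word)
  case_boundary <- function(i) {
    a <- substr(word, i, i)
    b <- substr(word, i + 1L, i + 1L)
    grepl("[[:upper:]]", a) != grepl("[[:upper:]]", b)
  }
  for (g in greek[order(-nchar(greek))]) {
    gl <- nchar(g)
    if (gl >= n) next
    if (startsWith(lw, g) && case_boundary(gl)) {
      return(c(substr(word, 1L, gl),
               split_greek_word(substr(word, gl + 1L, n), greek)))
    }
    if (endsWith(lw, g) && case_boundary(n - gl)) {
      return(c(split_greek_word(substr(word, 1L, n - gl), greek),
               substr(word, n - gl + 1L, n)))
    }
  }
  word
}

# Words of one token: punctuation becomes a separator; with
# `digit_greek = TRUE` the token is further split at letter/digit
# boundaries and at Greek-name boundaries.
token_words <- function(tok, digit_greek, greek) {
  x <- gsub("[^[:alnum:]]+", " ", tok)
  if (digit_greek) {
    x <- gsub("([[:alpha:]])([[:digit:]])", "\\1 \\2", x)
    x <- gsub("([[:digit:]])([[:alpha:]])", "\\1 \\2", x)
  }
  words <- strsplit(trimws(x), " +")[[1]]
  words <- words[nzchar(words)]
  if (digit_greek && length(words)) {
    words <- unlist(lapply(words, function(w) {
      if (grepl("^[[:alpha:]]+$", w)) split_greek_word(w, greek) else w
    }))
  }
  words
}

# Is a whitespace token invalid (to be dropped) at the given lexicon tier?
invalid_token <- function(tok, tier, tables) {
  lt <- tolower(tok)
  if (lt %in% tables$stopwords) return(TRUE)
  lex <- tables$bio_lexicon
  j <- match(lt, lex$term)
  !is.na(j) && !lex$keep[j] && lex$frequency[j] > tier
}

#' Generate normalized variations of a mention or synonym
#'
#' The deduplicated union, over the six lexicon frequency tiers, of the
#' editing cascade: parenthesis split into outside/inside parts; each part
#' split at invalid tokens (stopwords, and lexicon terms whose frequency
#' exceeds the active tier) into maximal runs of valid tokens; each run
#' rendered both without and with splitting at digit and Greek-letter
#' boundaries; punctuation dropped, words lowercased, sorted
#' alphabetically and joined by single spaces.
#'
#' @param text Non-empty string.
#' @param tables Symbol tables from [symbol_tables()].
#' @return Character vector of variation forms (lowercase, no consecutive
#'   spaces); may be empty when everything is filtered.
#' @examples
#' tabs <- symbol_tables(bio_lexicon = "synthetic")
#' generate_variations("YPK1 and YKR2(YPK2) genes", tabs)
#' @export
generate_variations <- function(text, tables) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  greek <- tables$greek_letters
  parts <- paren_parts(text)
  vars <- character(0)
  for (tier in tables$frequency_tiers) {
    for (part in parts) {
      toks <- strsplit(trimws(part), "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (!length(toks)) next
      invalid <- vapply(toks, invalid_token, logical(1), tier = tier,
                        tables = tables, USE.NAMES = FALSE)
      seg_id <- cumsum(invalid)
      for (seg in split(toks[!invalid], seg_id[!invalid])) {
        if (!length(seg)) next
        for (dg in c(FALSE, TRUE)) {
          words <- unlist(lapply(seg, token_words, digit_greek = dg,
                                 greek = greek))
          words <- tolower(words[nzchar(words)])
          if (length(words)) {
            vars <- c(vars, paste(sort(words, method = "radix"),
                                  collapse = " "))
          }
        }
      }
    }
  }
  unique(vars)
}

#' Build a dictionary store from gene records
#'
#' Every synonym of every record contributes all of its variations; one
#' variation form may map to several genes (ambiguity is preserved).
#'
#' @param records Gene records from [load_gene_info()].
#' @param tables Symbol tables.
#' @return An object of class `dictionary_store` with the variation map
#'   (`form`, `gene_id`, `source_synonym`) and the record table.
#' @export
build_dictionary <- function(records, tables) {
  stopifnot(nrow(records) > 0L)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    syns <- records$synonyms[[i]]
    per_syn <- lapply(syns, function(s) {
      forms <- generate_variations(s, tables)
      if (!length(forms)) return(NULL)
      data.frame(form = forms, gene_id = records$gene_id[i],
                 source_synonym = s, stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_syn)
  }
  variations <- do.call(rbind, rows)
  if (is.null(variations)) {
    variations <- data.frame(form = character(), gene_id = character(),
                             source_synonym = character(),
                             stringsAsFactors = FALSE)
  }
  variations <- variations[!duplicated(variations[c("form", "gene_id")]), ,
                           drop = FALSE]
  variations <- variations[order(variations$form, variations$gene_id,
                                 method = "radix"), , drop = FALSE]
  rownames(variations) <- NULL
  structure(list(taxon_id = records$taxon_id[1], variations = variations,
                 records = records),
            class = "dictionary_store")
}

#' @export
print.dictionary_store <- function(x, ...) {
  cat(sprintf("dictionary_store (taxon %s): %d genes, %d variation forms\n",
              x$taxon_id, nrow(x$records),
              length(unique(x$variations$form))))
  invisible(x)
}

#' Flexible (variation-based exact) matching of a mention
#'
#' Candidates are all genes whose synonym variation sets intersect the
#' mention's variation set. An empty result is a valid outcome.
#'
#' @param mention_text The mention's surface string.
#' @param store A `dictionary_store`.
#' @param tables Symbol tables.
#' @return A data.frame of candidates (`gene_id`, `matched_synonym`,
#'   `score`, `selected`), ordered by `gene_id`.
#' @export
flexible_match <- function(mention_text, store, tables) {
  forms <- generate_variations(mention_text, tables)
  hits <- store$variations[store$variations$form %in% forms, , drop = FALSE]
  hits <- hits[!duplicated(hits$gene_id), , drop = FALSE]
  hits <- hits[order(hits$gene_id, method = "radix"), , drop = FALSE]
  data.frame(gene_id = hits$gene_id, matched_synonym = hits$source_synonym,
             score = rep(0, nrow(hits)), selected = rep(FALSE, nrow(hits)),
             stringsAsFactors = FALSE)
}

#' Save a dictionary store as a two-file TSV bundle
#'
#' `variations.tsv` holds (form, gene_id, source synonym); `records.tsv`
#' holds the gene records with pipe-joined synonyms.
#'
#' @param store A `dictionary_store`.
#' @param dir Directory to write into (created if needed).
#' @return The directory, invisibly.
#' @export
save_dictionary <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(store$variations, file.path(dir, "variations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- data.frame(
    gene_id = store$records$gene_id,
    taxon_id = store$records$taxon_id,
    symbol = store$records$symbol,
    synonyms = vapply(store$records$synonyms, paste, "", collapse = "|"),
    stringsAsFactors = FALSE
  )
  utils::write.table(rec, file.path(dir, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a dictionary store saved by [save_dictionary()]
#'
#' @param dir Directory of the store.
#' @return A `dictionary_store`.
#' @export
load_dictionary <- function(dir) {
  variations <- utils::read.table(file.path(dir, "variations.tsv"),
                                  sep = "\t", header = TRUE,
                                  colClasses = "character",
                                  quote = "", comment.char = "")
  rec <- utils::read.table(file.path(dir, "records.tsv"),
                           sep = "\t", header = TRUE,
                           colClasses = "character",
                           quote = "", comment.char = "")
  records <- data.frame(
    gene_id = rec$gene_id, taxon_id = rec$taxon_id, symbol = rec$symbol,
    synonyms = I(strsplit(rec$synonyms, "|", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  variations <- variations[order(variations$form, variations$gene_id,
                                 method = "radix"), , drop = FALSE]
  rownames(variations) <- NULL
  structure(list(taxon_id = records$taxon_id[1], variations = variations,
                 records = records),
            class = "dictionary_store")
}
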