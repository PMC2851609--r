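#' Spelled-out Greek letter names
#'
#' The 24 English spellings of the Greek alphabet, used for the `g` shape
#' symbol and for Greek-aware splitting of synonyms.
#'
#' @format Character vector of length 24, lowercase.
#' @export
greek_letter_names <- c(
  "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta", "theta",
  "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron", "pi", "rho",
  "sigma", "tau", "upsilon", "phi", "chi", "psi", "omega"
)

#' Frequency tiers for biomedical-lexicon filtering
#'
#' Lexicon terms with a frequency strictly greater than the active tier are
#' filtered out of synonym variations; the tiers are swept from the most
#' restrictive (only very frequent terms removed) down to zero (all terms
#' removed), each tier contributing its own variations.
#'
#' @format Descending integer vector.
#' @export
frequency_tiers <- c(10000L, 1000L, 100L, 50L, 10L, 0L)

#' Read a stopword list
#'
#' One word per line, UTF-8; words are lowercased.
#'
#' @param file Path to a plain-text stopword file.
#' @return Character vector of lowercase stopwords.
#' @export
read_stopwords <- function(file) {
  words <- readLines(file, encoding = "UTF-8", warn = FALSE)
  words <- trimws(words)
  unique(tolower(words[nzchar(words)]))
}

#' Read a frequency-annotated biomedical lexicon
#'
#' Two or three TAB-separated columns: term, occurrence frequency, and an
#' optional flag (`gn` or `pr`) marking gene/protein terms that must never
#' be filtered from synonym variations.
#'
#' @param file Path to the TSV lexicon.
#' @return A data.frame with columns `term` (lowercase), `frequency`
#'   (non-negative integer) and `keep` (logical).
#' @export
read_bio_lexicon <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(term = character(), frequency = integer(),
                      keep = logical(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("bio-lexicon line %d: expected 'term<TAB>frequency'", bad[1]))
  }
  freq <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(freq) || any(freq < 0L)) {
    stop("bio-lexicon frequencies must be non-negative integers")
  }
  flag <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", "")
  data.frame(
    term = tolower(vapply(parts, `[[`, "", 1L)),
    frequency = freq,
    keep = flag %in% c("gn", "pr"),
    stringsAsFactors = FALSE
  )
}

#' Assemble the symbol tables used across the package
#'
#' Bundles the Greek-letter names, the stopword list, the
#' frequency-annotated biomedical lexicon and the fixed filtering tiers.
#' With no arguments, the stopword list bundled with the package and an
#' empty lexicon are used; the synthetic fixture lexicon shipped under
#' `extdata` can be requested with `bio_lexicon = "synthetic"`.
#'
#' @param stopwords Character vector of stopwords, or a path to a stopword
#'   file, or `NULL` for the bundled English list.
#' @param bio_lexicon A data.frame as returned by [read_bio_lexicon()], a
#'   path to a lexicon TSV, the string `"synthetic"` for the bundled
#'   fixture lexicon, or `NULL` for an empty lexicon.
#' @param greek_letters Character vector of spelled-out Greek names.
#' @return An object of class `symbol_tables`.
#' @export
symbol_tables <- function(stopwords = NULL, bio_lexicon = NULL,
                          greek_letters = greek_letter_names) {
  if (is.null(stopwords)) {
    stopwords <- read_stopwords(
      system.file("extdata", "stopwords_en.txt", package = "genenorm"))
  } else if (is.character(stopwords) && length(stopwords) == 1L &&
             file.exists(stopwords)) {
    stopwords <- read_stopwords(stopwords)
  } else {
    stopwords <- unique(tolower(stopwords))
  }
  if (is.null(bio_lexicon)) {
    bio_lexicon <- data.frame(term = character(), frequency = integer(),
                              keep = logical(), stringsAsFactors = FALSE)
  } else if (is.character(bio_lexicon) && length(bio_lexicon) == 1L) {
    path <- if (identical(bio_lexicon, "synthetic")) {
      system.file("extdata", "bio_lexicon_synthetic.tsv", package = "genenorm")
    } else {
      bio_lexicon
    }
    bio_lexicon <- read_bio_lexicon(path)
  }
  stopifnot(is.data.frame(bio_lexicon),
            all(c("term", "frequency", "keep") %in% names(bio_lexicon)))
  structure(
    list(
      greek_letters = tolower(greek_letters),
      stopwords = stopwords,
      bio_lexicon = bio_lexicon,
      frequency_tiers = frequency_tiers
    ),
    class = "symbol_tables"
  )
}

#' @export
print.symbol_tables <- function(x, ...) {
  cat("symbol_tables:",
      length(x$stopwords), "stopwords,",
      nrow(x$bio_lexicon), "lexicon terms,",
      length(x$greek_letters), "Greek names\n")
  invisible(x)
}
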