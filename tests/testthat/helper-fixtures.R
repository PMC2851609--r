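# Shared helpers: symbol tables with the bundled synthetic lexicon, and a
# tiny hand-built dictionary used across matcher and disambiguator tests.

test_tables <- function() symbol_tables(bio_lexicon = "synthetic")

# Three genes with punctuation/case synonym variants; bigram-similar
# within a gene, and one near-neighbor pair across genes (TNFA/TNFB) so
# labeled pair streams contain both classes.
toy_records <- function() {
  data.frame(
    gene_id = c("101", "202", "303"),
    taxon_id = "9606",
    symbol = c("TNFA", "YPK1", "TNFB"),
    synonyms = I(list(c("TNFA", "TNF-alpha", "TNF alpha", "tnfa"),
                      c("YPK1", "YPK-1", "ypk1"),
                      c("TNFB", "TNF-beta"))),
    stringsAsFactors = FALSE
  )
}

toy_store <- function(tables = test_tables()) {
  build_dictionary(toy_records(), tables)
}

random_sentence <- function(n_words, seed_words) {
  paste(sample(seed_words, n_words, replace = FALSE), collapse = " ")
}
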