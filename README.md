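# genenorm

Recognition and normalization of gene/protein mentions in biomedical
text, for text-mining pipelines that need both steps to be trainable on
the user's own corpora and organisms rather than tied to curated,
organism-specific resources.

The package implements three cooperating components:

* **A case-based-reasoning (CBR) tagger.** Training stores one *known
  case* per token — the tuple (token, category, preceding category,
  frequency), where category says whether the token sits inside a gold
  gene mention — and one *unknown case* per token **shape**, a string
  over `{A, a, 1, p, g, punctuation}`: `"Bmp4" → Aa1`,
  `"cGKI(alpha)" → aAAA(g)`, plus literal prefix/suffix forms such as
  `pat$a` and `a$vity` for lowercase words. Tagging retrieves the most
  similar case (verbatim token first, then shapes, then token parts) in
  forward and backward sweeps and takes the union; the highest
  frequency wins, ties fall to the negative class.
* **Dictionary normalization.** *Flexible matching* is exact matching
  on *variations*: lowercased, punctuation-stripped, alphabetically
  sorted forms produced by a tiered editing cascade that splits at
  parentheses, digits and Greek letters and filters stopwords and
  frequent biomedical-lexicon terms (tiers 10000, 1000, 100, 50, 10,
  0). *Machine-learning matching* classifies mention–synonym pairs:
  pairs are pre-selected by bigram/trigram Dice similarity (default
  threshold 0.9), described by pair features (prefix/suffix/number/
  Greek equality, n-gram similarity, one of five normalized string
  metrics — Smith-Waterman by default — and shape similarity) and
  classified by an SVM, random forest or logistic regression.
* **Disambiguation.** Competing identifiers are scored by comparing the
  article's token bag with each gene's *gene-document* (symbols,
  aliases, summaries, GO terms, ...) using the TF cosine, the number of
  common tokens, or their product (default). `single` selection keeps
  the argmax; `multiple` keeps every candidate scoring at least 50% of
  the maximum, a threshold recomputed per mention.

Corpora are read and written in the BioCreative 2 Gene Mention dialect
(`<id> <sentence>` plus `<id>|<start> <end>|<mention>`, offsets 0-based,
inclusive, counting non-space characters only); dictionaries are read
from Entrez `gene_info`-style TSV. Seeded fixture generators
(`fixture_spec()`, `synth_dictionary()`, `synth_corpus()`) let every
stage train and test without downloads.

## Worked example

```r
library(genenorm)
tabs <- symbol_tables(bio_lexicon = "synthetic")

# a seeded toy organism: 10 genes, 3 synonyms each, 60 annotated sentences
spec    <- fixture_spec(seed = 42, n_genes = 10, n_synonyms_per_gene = 3,
                        n_sentences = 60)
d       <- synth_dictionary(spec)
records <- load_gene_info(text = d$gene_info, taxon_id = d$taxon_id)
corpus  <- synth_corpus(spec, records)

base <- train_tagger(corpus$sentences, corpus$annotations, tabs, "demo")
base
#> case_base 'demo': 45 known cases, 31 unknown cases

text <- "We measured QEAYJDRZQO1 across replicate samples yesterday."
mentions <- tag(text, base, tabs)
mentions
#>          text start end
#> 1 QEAYJDRZQO1    10  20
```

The mention spans non-space characters 10–20 of the sentence (offsets
ignore spaces and are inclusive). Normalizing it against the toy
dictionary and gene-documents:

```r
store <- build_dictionary(records, tabs)
docs  <- load_gene_documents(text = d$gene_documents, records = records,
                             tables = tabs)
out <- normalize_mentions(mentions, text, store, tabs, docs = docs)
normalization_table(out, "demo")
#>   sentence_id start end     mention gene_id matched_synonym score selected
#> 1        demo    10  20 QEAYJDRZQO1  100001     QEAYJDRZQO1     0     TRUE
```

One candidate matched, so no disambiguation was needed and the score is
0. The building blocks are usable on their own:

```r
shape_of("cGKI(alpha)", tabs)
#> shape: aAAA(g)

generate_variations("YPK1 and YKR2(YPK2) genes", tabs)
#> [1] "ypk1"        "1 ypk"       "genes ykr2"  "2 genes ykr" "ypk2"
#> [6] "2 ypk"       "ykr2"        "2 ykr"

select_candidates(c(0.9, 0.7, 0.5, 0.4), "multiple")
#> $selected
#> [1]  TRUE  TRUE  TRUE FALSE
#> $threshold
#> [1] 0.45
```

With four candidates scoring 0.9/0.7/0.5/0.4, the multiple-selection
cut-off is 50% of the best score (0.45) and the first three candidates
are kept.

A thin command-line wrapper lives in `inst/cli/genenorm.R`
(`train-tagger`, `tag`, `build-lexicon`, `train-matcher`, `normalize`,
`fixtures`); it accepts full BioCreative-format corpora and Entrez
dictionaries unchanged if you have them.

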