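---
title: "Recognizing and normalizing gene mentions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing and normalizing gene mentions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genenorm)
```

## The problem

Biomedical text refers to genes and proteins with short symbols
("Bmp4"), descriptive names ("tumor necrosis factor"), and everything in
between, with punctuation, case and Greek-letter spellings varying
freely. Two tasks recur in any literature-mining pipeline: *recognition*
(find the spans of text that mention a gene or protein) and
*normalization* (map each span to a database identifier such as an
Entrez Gene ID). genenorm implements both as a trainable, organism-
agnostic pipeline: a case-based-reasoning (CBR) tagger for recognition,
dictionary matching (exact-on-variations or learned approximate
matching) for normalization, and a document-similarity step to pick
among competing identifiers.

## The CBR tagger

Training walks every token of every annotated sentence and stores
*cases*: a **known case** keeps the verbatim token, its category (inside
a gold gene mention or not), the category of the preceding token, and a
frequency counting repetitions; an **unknown case** keeps the token's
*shape* instead of its text, with the same remaining attributes. The
shape maps character classes to symbols — one `A` per uppercase letter
(acronym length is informative), one `a` per lowercase run, one `1` per
digit run, `p` for a stopword token, `g` for a spelled-out Greek letter,
punctuation kept literally — so "Bmp4" becomes `Aa1` and "cGKI(alpha)"
becomes `aAAA(g)`. Tokens made of five or more lowercase letters also
store a prefix form (`pat$a` for "patterning") and a suffix form
(`a$vity` for "activity"): the literal 3-letter prefix or 4-letter
suffix with the rest of the token abstracted away.

Tagging retrieves the most specific case available for each token:
verbatim token first, then the plain shape, then the prefix and suffix
forms, then the token's sub-parts (split at punctuation and letter/digit
boundaries). Among competing cases the highest frequency wins. Several
details are deliberate choices where more than one reading was
defensible:

* **Pass combination.** The tagger sweeps the sentence forward and then
  backward, each pass carrying its own running preceding-category
  context (the backward pass conditions on the token to the right). A
  token is positive when *either* pass marks it. The union is
  recall-oriented on purpose: the downstream normalizer tolerates a
  spurious mention (it simply finds no dictionary candidate) much
  better than it recovers a missed one.
* **Frequency ties** go to the negative class, biasing the tagger
  toward precision exactly where the evidence is balanced.
* **Sub-splitting** marks a token positive only when some part
  retrieves a positive case with frequency strictly greater than its
  negative retrieval — a conservative rule, since parts are weaker
  evidence than whole tokens.
* **Digit runs** collapse to a single `1` (mirroring the stated
  non-repetition of lowercase runs), so "IL12" is `AA1`.
* **Stopword status** applies to whole tokens only; Greek detection
  applies to case-homogeneous sub-tokens by table lookup against the 24
  English spellings.

Case bases persist as two TAB-separated text files per model, which
keeps trained models diffable and portable.

## Corpus format and offsets

Training corpora use the BioCreative 2 Gene Mention dialect: one file of
`<id> <sentence>` lines and one of `<id>|<start> <end>|<mention>` lines,
where offsets are 0-based, *inclusive at both ends*, and count only
non-space characters. `mention_offsets()` derives offsets from the
sentence text, the reader verifies the length invariant
`end - start + 1 == nchar(gsub(" ", "", text))` on every line, and
`char_offsets()` converts back to ordinary half-open character offsets
for interoperability. Overlapping gold mentions within one sentence are
rejected with an error — the format has no way to express which reading
is intended.

## Flexible matching and the variation cascade

Flexible matching is exact matching performed on *variations* rather
than surface strings. A variation is produced by an editing cascade:
split at parentheses into outside/inside parts; split each part at
invalid tokens (stopwords, and biomedical-lexicon terms whose corpus
frequency exceeds the active tier) into runs of valid tokens; within a
run, drop punctuation, optionally split at digit and Greek-letter
boundaries, lowercase, sort the words alphabetically and join with
single spaces. The cascade runs once per frequency tier (10000, 1000,
100, 50, 10, 0 — lower tiers filter more lexicon terms), and the
variation set is the union over tiers. "YPK1 and YKR2(YPK2) genes"
yields `ypk1`, `ykr2` and `ypk2` among its variations; "cGMP-gated
channel" yields both `cgmp channel gated` (at the tier where "channel"
survives) and `cgmp gated`.

Choices worth recording:

* Both the digit-split (`4 bmp`) and unsplit (`bmp4`) forms are
  emitted, maximizing the match surface while guaranteeing that every
  synonym matches itself.
* Greek splitting is guarded by a case boundary, so "TNFalpha" splits
  into TNF + alpha but "beta" is never cut at its embedded "eta".
* Lexicon terms flagged `gn`/`pr` (gene- and protein-type entries) are
  never filtered: filtering them away would delete exactly the material
  a mention is made of.
* Token validity is evaluated per tier at the whitespace-token level;
  words produced later by punctuation or digit splitting are not
  re-filtered.
* Word sorting uses byte-order (radix) comparison so stores are
  identical across locales.

A dictionary store is built from Entrez `gene_info`-style TSV (tax_id,
GeneID, Symbol, pipe-separated Synonyms, `-` for empty) and persists as
two TSV files: the variation map and the record table. One variation
form may map to several genes; that ambiguity is preserved for the
disambiguator.

## The trainable matcher

Approximate matching is a binary classification problem over
mention–synonym pairs. Each synonym is described by features (lowercased
3-letter prefix and suffix, first digit run, first Greek name, bigram
and trigram multisets, token shape); candidate pairs are selected when
their bigram or trigram Dice similarity reaches `pct_similarity`
(default 0.9); each selected pair is described by pair features —
equality of prefix/suffix/number/Greek parts, bigram and trigram
similarity, string similarity, and shape similarity (normalized edit
similarity of shape strings). Pairs of distinct synonyms of the same
gene are positive examples, all other selected pairs negative; negatives
are subsampled to 3 per positive (seeded) to keep classes balanced.
The classifier is an RBF SVM by default (random forest and logistic
regression are available); features are standardized by the SVM's
internal scaling.

The five string metrics are each normalized to [0, 1]: Levenshtein as
1 − d/max(len); Jaro-Winkler natively (prefix scale 0.1 over at most 4
characters); Smith-Waterman as the local alignment score (match 2,
mismatch −1, gap −1) divided by 2·min(len); Monge-Elkan over whitespace
tokens with a Jaro-Winkler inner metric, averaged over both directions;
Soft-TFIDF with partner threshold 0.9 and IDF statistics taken from the
dictionary's synonym set (uniform weights when no corpus is supplied).
Dice over n-gram multisets implements "percentage of grams in common":
it is symmetric, bounded and standard. All comparisons are lowercased;
the n-gram computation is lowercased by construction, so pure case
variants have similarity 1.

## Disambiguation

Every gene carries a *gene-document*: the lowercased, stopword-filtered
token bag of its symbols, aliases, descriptions, summaries, GO names and
related annotation fields, loaded from a three-column TSV. A mention
with several candidates is resolved by comparing the article's token bag
against each candidate's gene-document with one of three scores: the
term-frequency cosine, the number of distinct common tokens, or their
product (the default — it rewards both directions of agreement). Single
selection keeps the argmax (all tied candidates on a tie — the
ambiguity is real and callers should see it); multiple selection keeps
every candidate scoring at least 50% of the maximum, a relative
threshold recomputed per mention (scores 0.9/0.7/0.5/0.4 give cut-off
0.45 and keep the first three). A mention with exactly one candidate is
selected with score 0: no disambiguation happened, and the zero makes
that visible. If every score is 0 in multiple mode, all candidates pass
the threshold 0 — a documented edge case. Candidates are ordered by
descending score, then gene id, so output is deterministic.

## The fixture generators

Real training resources (BioCreative corpora, full organism
dictionaries, BioThesaurus) are large, licensed or remote, so the
package ships seeded generators that reproduce the *statistical
structure* the method relies on, at desk scale:

* **Dictionaries** organize genes into families of up to five members
  sharing a random 10-letter symbol stem and differing in a member
  digit, emulating paralog nomenclature (SLC-family style). Synonyms
  come from perturbation operators (case flip, hyphen insertion before
  the digit, extra digit suffix, appended Greek letter, token
  reordering), so same-gene pairs are near neighbors under n-gram
  similarity. The family structure matters: cross-gene members are near
  neighbors too, which is what gives the matcher's training stream its
  negative class even at the strict default selection threshold.
* **Gene-documents** draw 30 unique random words per gene from disjoint
  vocabularies, so disambiguation is solvable by construction and any
  failure is an implementation defect, not noise.
* **Corpora** embed synonyms into three fixed sentence templates with
  the mention at the start, middle and end, so the preceding-category
  attribute takes both values; context words never collide with
  synonyms, making every token unambiguous. Under these conditions the
  tagger must reproduce its training annotations byte-for-byte — the
  memorization property tested in the suite.
* An `ambiguity_rate` adds synonyms shared between gene pairs; the
  generating (owner) gene is recorded so selection accuracy can be
  scored.

What the fixtures do *not* emulate: linguistic variety, genuinely
ambiguous common-word gene names ("deafness"), noisy annotation
boundaries, or the long-tailed frequency structure of real corpora.
Passing the fixture suites therefore demonstrates that the mechanics —
case retrieval, the variation cascade, pair classification, relative
thresholding — are implemented correctly, not that benchmark-level
accuracy on real corpora is reached; published results at corpus scale
require the original training resources, which the readers and the CLI
accept unchanged if supplied.

## Problem sizes and numerics

The test suite trains on fixtures of 5–50 genes, 3–4 synonyms per gene
and up to 60 sentences, and evaluates the matcher with a 30% seeded
holdout over a few hundred pairs; each suite runs in seconds. Selection
thresholds are compared with `>=`, so a pair exactly at the threshold
is kept. All randomness flows through explicit seeds (`with_seed`
restores the caller's RNG state), and all persisted artifacts are plain
text except the fitted matcher, which is serialized as RDS at run time.

## Known limitations

* No sentence splitting or part-of-speech analysis: input is assumed to
  be sentence- or abstract-level plain text.
* The tagger's backward-pass semantics and pass-combination rule are
  one defensible reading of a two-pass sliding-window description;
  alternatives (intersection, refinement) would trade recall for
  precision.
* `common_tokens` uses type (set) semantics; occurrence counting would
  weight repeated vocabulary more heavily.
* The variation cascade can blow up on very long synonym lists with
  many parentheses; dictionaries at fixture scale build in well under a
  second, but genome-scale dictionaries are better built once and
  persisted.
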