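# Seeded fixture generators. They produce toy organism dictionaries,
# gene-document stores and annotated corpora with the statistical
# structure the method exploits: same-gene synonyms are near neighbors
# under n-gram similarity, genes within a family share a long symbol stem
# (so near-duplicate cross-gene pairs exist), gene-documents have
# separable vocabularies, and corpus tokens are unambiguous. Everything is
# deterministic per seed.

#' Fixture specification
#'
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param n_genes Number of genes.
#' @param n_synonyms_per_gene Synonyms per gene (the symbol counts as the
#'   first).
#' @param perturbation_ops Operators generating synonyms from the symbol:
#'   `case_flip`, `punctuation_insert`, `number_suffix`,
#'   `greek_spell_swap`, `token_reorder`.
#' @param n_sentences Sentences in the synthetic corpus.
#' @param ambiguity_rate Fraction in \[0, 1) controlling how many extra
#'   synonyms are shared between two genes.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 10L, n_synonyms_per_gene = 3L,
                         perturbation_ops = c("case_flip",
                                              "punctuation_insert",
                                              "number_suffix",
                                              "greek_spell_swap",
                                              "token_reorder"),
                         n_sentences = 30L, ambiguity_rate = 0) {
  perturbation_ops <- match.arg(perturbation_ops, several.ok = TRUE)
  stopifnot(n_genes >= 1L, n_synonyms_per_gene >= 1L, n_sentences >= 0L,
            ambiguity_rate >= 0, ambiguity_rate < 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_synonyms_per_gene = as.integer(n_synonyms_per_gene),
                 perturbation_ops = perturbation_ops,
                 n_sentences = as.integer(n_sentences),
                 ambiguity_rate = ambiguity_rate),
            class = "fixture_spec")
}

FIXTURE_TAXON <- "99999"

random_upper <- function(n) {
  paste(sample(LETTERS, n, replace = TRUE), collapse = "")
}

random_lower_word <- function(n) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

unique_strings <- function(k, gen) {
  out <- character(0)
  while (length(out) < k) {
    out <- unique(c(out, vapply(seq_len(k - length(out)),
                                function(i) gen(), "")))
  }
  out
}

# Synonym perturbation operators. Symbols are <STEM><member digit>, stems
# 10 uppercase letters, so every operator output stays a near neighbor of
# the symbol under bigram similarity.
perturb_synonym <- function(symbol, op, gene_index) {
  switch(op,
    case_flip = chartr(paste(c(LETTERS, letters), collapse = ""),
                       paste(c(letters, LETTERS), collapse = ""), symbol),
    punctuation_insert = sub("([0-9]+)$", "-\\1", symbol),
    number_suffix = paste0(symbol, "2"),
    greek_spell_swap = paste0(
      symbol, "-", greek_letter_names[(gene_index - 1L) %% 24L + 1L]),
    token_reorder = {
      m <- regmatches(symbol, regexpr("[0-9]+$", symbol))
      if (length(m)) {
        paste(m, sub("[0-9]+$", "", symbol))
      } else {
        paste(rev(ws_tokens(symbol)), collapse = " ")
      }
    }
  )
}

#' Generate a synthetic organism dictionary and gene-documents
#'
#' Genes are grouped into families of up to five members sharing a
#' 10-letter symbol stem and differing in a member digit (emulating
#' paralog nomenclature); synonyms are produced by the requested
#' perturbation operators, so same-gene pairs are near neighbors under
#' n-gram similarity while cross-gene near pairs only arise within a
#' family. Gene-documents draw on disjoint per-gene vocabularies so
#' disambiguation is solvable. With `ambiguity_rate > 0`, extra synonyms
#' are shared between gene pairs (the odd-indexed gene of each pair being
#' the generating owner).
#'
#' @param spec A `fixture_spec`.
#' @return A list with `gene_info` (gene_info-dialect TSV lines),
#'   `gene_documents` (gene-document TSV lines), `taxon_id` and
#'   `owners` (named character vector mapping each shared synonym to its
#'   generating gene id).
#' @export
synth_dictionary <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_genes
    n_fam <- ceiling(n / 5L)
    stems <- unique_strings(n_fam, function() random_upper(10L))
    fam <- rep(seq_len(n_fam), each = 5L)[seq_len(n)]
    member <- unlist(lapply(table(fam), seq_len), use.names = FALSE)
    symbol <- paste0(stems[fam], member)
    gene_id <- sprintf("%d", 100000L + seq_len(n))
    ops <- spec$perturbation_ops
    synonyms <- lapply(seq_len(n), function(i) {
      syns <- symbol[i]
      k <- 2L
      while (length(syns) < spec$n_synonyms_per_gene) {
        op <- ops[(k - 2L) %% length(ops) + 1L]
        cand <- perturb_synonym(symbol[i], op, i)
        if (!cand %in% syns) syns <- c(syns, cand)
        k <- k + 1L
        if (k > 2L + 2L * length(ops)) break
      }
      syns
    })
    owners <- character(0)
    n_shared <- ceiling(spec$ambiguity_rate * n / 2L)
    if (n_shared > 0L && n >= 2L) {
      shared_names <- unique_strings(n_shared, function() {
        paste0(random_upper(8L), sample(9L, 1L))
      })
      for (k in seq_len(n_shared)) {
        i <- (2L * k - 1L - 1L) %% n + 1L
        j <- (2L * k - 1L) %% n + 1L
        synonyms[[i]] <- c(synonyms[[i]], shared_names[k])
        synonyms[[j]] <- c(synonyms[[j]], shared_names[k])
        owners[shared_names[k]] <- gene_id[i]
      }
    }
    gene_info <- vapply(seq_len(n), function(i) {
      syn_field <- setdiff(synonyms[[i]], symbol[i])
      paste(c(FIXTURE_TAXON, gene_id[i], symbol[i], "-",
              if (length(syn_field)) paste(syn_field, collapse = "|")
              else "-",
              rep("-", 11L)), collapse = "\t")
    }, "")
    vocab <- unique_strings(30L * n, function() random_lower_word(7L))
    vocab_by_gene <- split(vocab, rep(seq_len(n), each = 30L))
    gene_documents <- unlist(lapply(seq_len(n), function(i) {
      w <- vocab_by_gene[[i]]
      c(paste(gene_id[i], "summary", paste(w[1:15], collapse = " "),
              sep = "\t"),
        paste(gene_id[i], "go", paste(w[16:25], collapse = " "),
              sep = "\t"),
        paste(gene_id[i], "phenotype", paste(w[26:30], collapse = " "),
              sep = "\t"))
    }))
    list(gene_info = gene_info, gene_documents = gene_documents,
         taxon_id = FIXTURE_TAXON, owners = owners)
  })
}

corpus_templates <- c(
  "%s modulates cellular stress response signaling.",
  "We measured %s across replicate samples yesterday.",
  "Observed downstream signaling depends on %s."
)

#' Generate an annotated synthetic corpus
#'
#' Embeds the dictionary's synonyms into template sentences (mention at
#' the start, middle or end, so the preceding-category attribute takes
#' both values during training); annotations are computed with
#' [mention_offsets()] and satisfy the corpus format invariant. Context
#' words never occur inside a mention, so every token is unambiguous.
#'
#' @param spec A `fixture_spec` (`n_sentences` sentences are produced).
#' @param records Gene records from [load_gene_info()] applied to the
#'   synthetic dictionary.
#' @return A list with `sentences` and `annotations` data.frames in the
#'   corpus dialect.
#' @export
synth_corpus <- function(spec, records) {
  stopifnot(nrow(records) > 0L)
  syns <- unlist(records$synonyms)
  sentences <- data.frame(sentence_id = character(), text = character(),
                          stringsAsFactors = FALSE)
  annotations <- data.frame(sentence_id = character(), start = integer(),
                            end = integer(), text = character(),
                            stringsAsFactors = FALSE)
  if (spec$n_sentences == 0L) {
    return(list(sentences = sentences, annotations = annotations))
  }
  for (i in seq_len(spec$n_sentences)) {
    syn <- syns[(i - 1L) %% length(syns) + 1L]
    template <- corpus_templates[(i - 1L) %% length(corpus_templates) + 1L]
    text <- sprintf(template, syn)
    id <- sprintf("S%05d", i)
    off <- mention_offsets(text, syn)
    sentences <- rbind(sentences,
                       data.frame(sentence_id = id, text = text,
                                  stringsAsFactors = FALSE))
    annotations <- rbind(annotations,
                         data.frame(sentence_id = id,
                                    start = unname(off["start"]),
                                    end = unname(off["end"]),
                                    text = syn, stringsAsFactors = FALSE))
  }
  list(sentences = sentences, annotations = annotations)
}

#' The pinned worked-example sentence and its annotations
#'
#' Returns the training-corpus sentence P00030937A0119 together with its
#' three gene mentions; the offsets are recomputed from the sentence text
#' with [mention_offsets()], not hard-coded, so the bundle doubles as a
#' regression check of the offset convention.
#'
#' @return A list with a one-row `sentence` data.frame and a three-row
#'   `annotations` data.frame.
#' @export
worked_example_bundle <- function() {
  id <- "P00030937A0119"
  text <- paste("SGPT, SGOT, and alkaline phosphatase concentrations",
                "were essentially normal in all subjects.")
  mentions <- c("SGPT", "SGOT", "alkaline phosphatase")
  offs <- lapply(mentions, function(m) mention_offsets(text, m))
  list(
    sentence = data.frame(sentence_id = id, text = text,
                          stringsAsFactors = FALSE),
    annotations = data.frame(
      sentence_id = id,
      start = vapply(offs, `[[`, 0L, "start"),
      end = vapply(offs, `[[`, 0L, "end"),
      text = mentions, stringsAsFactors = FALSE)
  )
}
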