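---
title: "Silver-standard labels for validating machine keyphrase extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silver-standard labels for validating machine keyphrase extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silverlabels)
```

## The problem

Unsupervised keyphrase extractors (YAKE and its relatives) are routinely
run over corpora of research-proposal abstracts to index what a facility's
users actually work on. Validating their output is hard precisely where it
matters: such corpora have no gold-standard keyword annotations, and
hand-labeling hundreds of technical abstracts is not realistic.

`silverlabels` implements two automated routes to *silver-standard*
labels — labels derived mechanically, trusted enough to rank extractor
configurations even though they are neither complete nor perfectly clean —
plus the evaluation and tuning machinery that consumes them:

1. **Artifact linkage.** Some proposals are linked, through shared
   identifiers, to the publications they produced. Those publications carry
   author keywords and controlled indexing terms (Web of Science author
   keywords, PubMed author keywords, MeSH terms). Pooled and filtered,
   these become labels for the linked documents.
2. **Ontology annotation.** Domain ontologies contribute a term lexicon.
   Matching it against the text yields candidate labels for *every*
   document; a document-frequency filter keeps the rare, and therefore
   discriminating, ones.

## Shared text normalization

Every route runs on the same normalized view of the text, built by
`prepare_corpus()`:

* `clean_text()` removes URLs, parenthetical author–year and bracketed
  numeric citations, standalone numbers, and punctuation (hyphens and
  slashes become token separators). Alphanumeric tokens like "C4" survive;
  case is preserved. The function is idempotent.
* `tokenize()` splits on alphanumeric runs and records each token's
  0-based, half-open character span, so every downstream match can point
  back at its verbatim surface.
* `porter_stem()` maps tokens to Porter stems (the widely used variant
  with the irregular-form pool and the extra `li`-suffix rules, matched
  against a reference implementation at development time).
  `stem_phrase()` applies the same normalization to whole phrases:
  lowercase, strip punctuation, stem each token, join with single spaces.

All comparisons anywhere in the package happen between stemmed phrases, so
"genome" matches "genomes" but nothing partial ever matches: a stemmed
phrase is an atom.

## Route 1: labels from linked publications

`derive_publication_labels()` composes three steps, each exported:

* `link_by_id()` joins documents to keyword records through shared IDs
  (many-to-many; dangling links are counted, not fatal).
* `pool_keywords()` takes the union of the per-source keyword lists over a
  document's records, deduplicated on the stemmed phrase; the first-seen
  surface form represents each stem.
* `filter_keywords_in_text()` keeps a keyword only if its stemmed token
  sequence occurs *contiguously* in the document's stem sequence. This is
  the quality gate: author keywords often describe the publication rather
  than the proposal, and a keyword absent from the proposal text cannot be
  recovered by any extractor, so scoring against it would only add noise.

The result is a tidy label table (`doc_id`, `phrase`, `stem`, `source`,
`score`) covering the linked subset of the corpus.

## Route 2: labels from ontology annotation

`derive_ontology_labels()` composes the second pipeline:

* `read_ontology()` loads OBO Graphs JSON or a flat TSV dialect and merges
  sources into one is-a graph (validated: unique IDs, no dangling edges,
  acyclic).
* `prune_branches()` restricts each source to the is-a descendants of
  curated keep-roots *before* any matching. Broad upper-level branches
  ("data handling", measurement units) otherwise flood the annotation with
  generic hits. A term reachable from both a kept and a removed root is
  kept (any-ancestor rule).
* `build_lexicon()` turns every term label and synonym into a stemmed
  lexicon entry; one stem may map to several term IDs.
* `annotate_corpus()` scans each document greedily left to right, longest
  entry first (up to `max_len = 4` tokens), so nested sub-matches are
  suppressed and matches never overlap. Spans are recorded against
  `clean_text`.
* `filter_short()` drops single-token matches under three characters
  unless they are all-caps acronyms ("of" goes, "DNA" stays).
* `pos_filter()` optionally keeps only matches whose head token (the final
  token of the span) is tagged noun-like. No tagger ships with the
  package; any `function(tokens) -> tags` plugs in, and a stemmed
  blocklist works without one. A tagger error skips the stage with a
  warning rather than failing the run.
* `build_df_index()` and `apply_df_threshold()` implement the ranking
  rule: a stem is kept at threshold *t* iff its document count is at most
  `max(1, ceiling(t * N))`. Common terms ("sample", "data") appear
  everywhere and say nothing about a particular document; rarity is used
  as a proxy for specificity. At *t* = 1% over a 184-document corpus the
  cutoff is two documents; *t* = 100% keeps everything, and label counts
  grow monotonically with *t*.

## Evaluation and tuning

`evaluate_corpus()` scores a ranked keyword table against a label table.
For each document with at least one label and one keyword, the top-*N*
phrases (*N* in {5, 10, 20} by default) are stemmed, deduplicated, and
exact-matched against the label stems; precision, recall and F-1 use the
0/0 → 0 convention and are macro-averaged (micro-averaging is available).
Documents missing either side are skipped and listed with reasons —
never silently divided by zero. The result is a `keyphrase_eval` object
with broom-style `tidy()` (per-document) and `glance()` (one-row
aggregate) methods and an `autoplot()`.

`grid_search()` enumerates the full Cartesian product of extractor
hyperparameters — by default n-gram length 1–3, window 1–3, three
deduplication metrics, five thresholds: 135 combinations — in
lexicographic order, scores each, and reports the per-*N* argmax of
aggregate F-1. Ties resolve to the lexicographically smallest combination
and all tied winners are listed, so the report never hides a plateau.

Extractors are pluggable: `register_extractor()` accepts any
`function(clean_text, params) -> character`, which is how externally
produced output (e.g. a Python YAKE run, read back via
`read_keywords_json()`) enters the pipeline. A deterministic built-in
`"frequency"` extractor makes the whole machinery testable offline.

## Synthetic corpora as a test instrument

`generate_corpus()` builds a seeded corpus of pseudo-word documents with
*planted* label phrases woven verbatim into the semantic fields, keyword
records that carry those phrases (sometimes inflected) plus distractor
keywords verifiably absent from the text, and a toy ontology whose kept
branches hold the planted phrases and whose decoy branches hold filler
vocabulary. Because the generator's ground truth is known by construction,
end-to-end properties become testable: the publication route must recover
the planted stems exactly, an oracle extractor must score F-1 = 1.0, and
branch pruning must have an observable effect. The generator's defaults
mirror realistic study conditions (40% of documents linked, ~85/14/1%
uni/bi/trigram label composition).

## Descriptive statistics

`label_stats()` summarizes any label table: n-gram composition
(`ngram_summary()`), a document-frequency histogram over distinct stems
(`frequency_summary()`), within-document co-occurrence counts
(`cooccurrence_counts()`), and pairwise cosine-similarity summaries of
within-document label pairs (`pairwise_similarity()`), given any embedding
adapter — `hash_embedding()` provides a deterministic synthetic one.

## Worked example

```{r worked-example}
we <- worked_example()

# stemmed exact matching, document 1
match_keywords(
  we$ml_keyphrases$phrase[we$ml_keyphrases$doc_id == "1"],
  we$publication_labels[we$publication_labels$doc_id == "1", ])

ev <- evaluate_corpus(we$publication_labels, we$ml_keyphrases)
ev
glance(ev)
```

Note the full-phrase rule at work in document 3: the extractor produced
`"evolut"`, the label list contains `"evolut of symbiosi"`, and no match
is awarded.

## Known limitations

* Publication labels exist only for the linked subset of a corpus, and an
  author keyword absent from the proposal text is dropped even when it is
  a fair description of the work — silver, not gold.
* The rarity rule discards common-but-correct ontology labels by design;
  the threshold trades recall for specificity.
* Stemmed exact matching gives no credit for synonyms or paraphrases
  unless an ontology synonym maps them to the same entry.
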