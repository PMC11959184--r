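# silverlabels

Silver-standard label derivation and keyphrase validation for unlabeled
scientific text.

## The science

Facilities that review thousands of research proposals increasingly index
them with unsupervised keyphrase extractors (YAKE and its relatives). The
catch is validation: proposal corpora have no gold-standard keyword
annotations, and hand-labeling hundreds of dense technical abstracts is
impractical. Without labels there is no way to choose between the dozens
of extractor configurations — n-gram length, context window,
deduplication metric and threshold — that all produce plausible-looking
keyword lists.

`silverlabels` implements two automated routes to *silver-standard*
labels: labels derived mechanically, imperfect but trustworthy enough to
rank extractor configurations.

1. **Artifact linkage** (`derive_publication_labels()`). A subset of
   proposals is linked, via shared identifiers, to the publications they
   produced. Author keywords and controlled indexing terms from those
   publications (Web of Science author keywords, PubMed author keywords,
   MeSH terms) are pooled per document, deduplicated on Porter stems, and
   filtered to keywords whose stemmed token sequence actually occurs
   contiguously in the proposal text — a keyword the text never states
   cannot be recovered by any extractor and would only add noise.
2. **Ontology annotation** (`derive_ontology_labels()`). Domain
   ontologies are pruned to curated is-a branches, their term labels and
   synonyms become a stemmed lexicon, and each document is annotated by
   greedy leftmost-longest matching. A document-frequency rule then keeps
   only rare stems — at threshold *t* over *N* documents, those in at most
   `max(1, ceiling(t * N))` documents — using rarity as a proxy for
   specificity. This route labels *every* document, not just the linked
   subset.

Machine keyphrases are validated against either label set by **stemmed
full-phrase exact matching** (`evaluate_corpus()`): "genomes" matches the
label "genome", but "evolut" earns nothing against the label
"evolut of symbiosi". Precision/recall/F-1 at top-5/10/20 are
macro-averaged, and `grid_search()` sweeps the full 135-combination
hyperparameter grid to find the best extractor configuration per cutoff.

A seeded synthetic-corpus generator (`generate_corpus()`) plants known
label phrases into pseudo-word documents, records, and a toy ontology, so
every pipeline stage is testable offline against ground truth known by
construction.

## Worked example

The package bundles three genomics proposals with their derived labels
and the top-10 machine keyphrases an extractor produced for each (all in
stemmed form, as such results are customarily reported).

```r
library(silverlabels)
we <- worked_example()

match_keywords(
  we$ml_keyphrases$phrase[we$ml_keyphrases$doc_id == "1"],
  we$publication_labels[we$publication_labels$doc_id == "1", ])
#> [1] "desulfitobacterium" "genom"

ev <- evaluate_corpus(we$publication_labels, we$ml_keyphrases)
ev
#> <keyphrase_eval: 3 document(s) scored, macro-averaged>
#> # A tibble: 3 × 4
#>       n precision recall     f1
#>   <int>     <dbl>  <dbl>  <dbl>
#> 1     5    0.0667  0.167 0.0952
#> 2    10    0.233   0.583 0.310
#> 3    20    0.233   0.583 0.310

tidy(ev)      # per-document scores, one row per document per cutoff
#> # A tibble: 9 × 8
#>   doc_id     n n_matched n_extracted n_labels precision recall    f1
#>   <chr>  <int>     <int>       <int>    <int>     <dbl>  <dbl> <dbl>
#> 1 1          5         1           5        2       0.2    0.5 0.286
#> 2 1         10         2          10        2       0.2    1   0.333
#> 3 1         20         2          10        2       0.2    1   0.333
#> 4 2          5         0           5        8       0      0   0
#> # ℹ 5 more rows
```

`glance(ev)` gives the aggregate as one wide row; `autoplot(ev)` plots
scores against the cutoff.

## End-to-end on synthetic data

```r
sim <- generate_corpus(synthetic_spec(seed = 1))

# route 1: labels inherited from linked records
pub <- derive_publication_labels(sim$corpus, sim$records)
pub
#> # A tibble: 110 × 5
#>    doc_id phrase       stem         source      score
#>    <chr>  <chr>        <chr>        <chr>       <dbl>
#>  1 DOC002 koki         koki         publication    NA
#>  2 DOC002 paskix kotom paskix kotom publication    NA
#>  3 DOC002 gruplem      gruplem      publication    NA
#> # ℹ 107 more rows

# route 2: ontology annotation, pruned to kept branches, DF-filtered
onto <- derive_ontology_labels(sim$corpus, sim$ontology,
                               keep_roots = sim$keep_roots,
                               threshold = 0.05)

# tune the built-in frequency extractor against the planted labels
grid <- grid_search(sim$corpus, sim$ground_truth)
glance(grid)
```

Real extractor output plugs in the same way: register an adapter with
`register_extractor("yake", function(clean_text, params) ...)`, or read a
JSON file of pre-computed keyword lists with `read_keywords_json()` and
pass it straight to `evaluate_corpus()`.

A command-line front end covering the full pipeline
(simulate / prepare / derive labels / extract / evaluate / tune / stats)
ships at `inst/cli/silverlabels`, configured by a YAML file.

## Reproduction

All randomness is seed-controlled. To reproduce the acceptance run:

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON output contains the worked-example evaluation and matched label
sets, the document-frequency boundary count, grid cardinality and per-N
winners, and the synthetic end-to-end results (exact publication-label
recovery rate, oracle-extractor F-1, label counts across DF thresholds).
The test suite runs with:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "silverlabels", load_package = "installed")'
```

## Package layout

| Area | Functions |
|---|---|
| Corpus I/O & normalization | `read_document_table()`, `clean_text()`, `tokenize()`, `prepare_corpus()`, `read_keyword_records()` |
| Stemming | `porter_stem()`, `stem_phrase()` |
| Publication labels | `link_by_id()`, `pool_keywords()`, `filter_keywords_in_text()`, `derive_publication_labels()` |
| Ontology labels | `read_ontology()`, `prune_branches()`, `build_lexicon()`, `annotate_corpus()`, `filter_short()`, `pos_filter()`, `build_df_index()`, `apply_df_threshold()`, `derive_ontology_labels()` |
| Extraction | `extractor_params()`, `register_extractor()`, `extract_keywords()`, `batch_extract()`, `read_keywords_json()` |
| Evaluation & tuning | `match_keywords()`, `f1_score()`, `prf()`, `evaluate_corpus()`, `grid_search()` (+ `tidy()`, `glance()`, `autoplot()`) |
| Label statistics | `ngram_summary()`, `frequency_summary()`, `cooccurrence_counts()`, `pairwise_similarity()`, `label_stats()` |
| Synthetic data | `synthetic_spec()`, `generate_corpus()`, `generate_toy_ontology()`, `write_synthetic_files()` |

The methods vignette (`vignettes/silver-standard-labels.Rmd`) documents
the design decisions: why absent keywords are filtered, why rarity stands
in for specificity, the greedy-matching and threshold semantics, and the
known limitations of silver-standard labels.
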