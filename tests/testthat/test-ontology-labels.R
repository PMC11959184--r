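test_that("ontology construction validates terms, edges, and acyclicity", {
  onto <- chain_ontology()
  expect_s3_class(onto, "ontology")
  expect_error(ontology(
    tibble::tibble(term_id = c("A", "A"), label = c("x", "y"),
                   synonyms = list(character(), character()),
                   source = "t"),
    tibble::tibble(child = character(), parent = character())),
    "duplicate term_id")
  expect_error(ontology(
    tibble::tibble(term_id = "A", label = "x",
                   synonyms = list(character()), source = "t"),
    tibble::tibble(child = "A", parent = "Z")),
    "not in terms")
  expect_error(ontology(
    tibble::tibble(term_id = c("A", "B"), label = c("x", "y"),
                   synonyms = list(character(), character()),
                   source = "t"),
    tibble::tibble(child = c("A", "B"), parent = c("B", "A"))),
    "cycle")
})

test_that("ontologies round-trip through the TSV dialect", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "onto.tsv")
  onto <- ontology(
    tibble::tibble(
      term_id = c("T:1", "T:2"),
      label = c("cellulose degradation", "sorghum"),
      synonyms = list(c("cellulolysis"), character()),
      source = "toy"),
    tibble::tibble(child = "T:2", parent = "T:1")
  )
  write_ontology_tsv(onto, path)
  back <- read_ontology(path)
  expect_equal(back$terms$term_id, onto$terms$term_id)
  expect_equal(back$terms$synonyms, onto$terms$synonyms)
  expect_equal(back$edges, onto$edges)
})

test_that("OBO Graphs JSON loads with is-a edges only", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "onto.json")
  jsonlite::write_json(list(graphs = list(list(
    id = "toy.json",
    nodes = list(
      list(id = "T:1", lbl = "fungus",
           meta = list(synonyms = list(list(val = "fungi")))),
      list(id = "T:2", lbl = "amanita")
    ),
    edges = list(
      list(sub = "T:2", pred = "is_a", obj = "T:1"),
      list(sub = "T:2", pred = "part_of", obj = "T:1")
    )
  ))), path, auto_unbox = TRUE)
  onto <- read_ontology(path)
  expect_equal(nrow(onto$terms), 2L)
  expect_equal(onto$terms$synonyms[[1]], "fungi")
  expect_equal(nrow(onto$edges), 1L)
})

test_that("prune_branches keeps descendants of the roots, inclusive", {
  onto <- chain_ontology()
  pruned <- prune_branches(onto, list(toy = "B"))
  expect_setequal(pruned$terms$term_id, c("B", "C"))
  expect_equal(pruned$edges, tibble::tibble(child = "C", parent = "B"))
  # unknown roots are fatal, sources without roots are kept whole
  expect_error(prune_branches(onto, list(toy = "Z")), "unknown keep-root")
  expect_equal(nrow(prune_branches(onto, list(other = character()))$terms),
               3L)
})

test_that("a term under both a kept and a removed branch is retained", {
  onto <- ontology(
    tibble::tibble(
      term_id = c("KEEP", "DROP", "X"),
      label = c("keep root", "drop root", "shared leaf"),
      synonyms = list(character(), character(), character()),
      source = "toy"),
    tibble::tibble(child = c("X", "X"), parent = c("KEEP", "DROP"))
  )
  pruned <- prune_branches(onto, list(toy = "KEEP"))
  expect_setequal(pruned$terms$term_id, c("KEEP", "X"))
})

test_that("build_lexicon stems labels and synonyms, merging term IDs", {
  onto <- ontology(
    tibble::tibble(
      term_id = c("T:1", "T:2", "T:3"),
      label = c("cellulose degradation", "Degrading Cellulose!", ""),
      synonyms = list("sorghum", character(), character()),
      source = "toy"),
    tibble::tibble(child = character(), parent = character())
  )
  expect_warning(lex <- build_lexicon(onto), "empty labels")
  expect_setequal(lex$entry_stem,
                  c("cellulos degrad", "degrad cellulos", "sorghum"))
  expect_equal(lex$n_tokens[lex$entry_stem == "sorghum"], 1L)
  expect_equal(lex$term_ids[lex$entry_stem == "sorghum"][[1]], "T:1")
})

test_that("annotation is greedy leftmost-longest with verbatim surfaces", {
  corpus <- corpus_from_texts(list(
    d = "Cellulose degradation by Amanita thiersii affects cellulose."))
  onto <- ontology(
    tibble::tibble(
      term_id = c("T:1", "T:2", "T:3"),
      label = c("cellulose degradation", "cellulose", "Amanita thiersii"),
      synonyms = list(character(), character(), character()),
      source = "toy"),
    tibble::tibble(child = character(), parent = character())
  )
  m <- annotate_corpus(corpus, build_lexicon(onto))
  # the bigram wins over its nested unigram; the trailing unigram matches
  expect_equal(m$entry_stem,
               c("cellulos degrad", "amanita thiersii", "cellulos"))
  expect_equal(m$surface,
               c("Cellulose degradation", "Amanita thiersii", "cellulose"))
  recovered <- substr(rep(corpus$clean_text, nrow(m)), m$start + 1L, m$end)
  expect_equal(recovered, m$surface)
  expect_equal(m$term_ids, list("T:1", "T:3", "T:2"))
})

test_that("annotation agrees with the brute-force oracle on random docs", {
  set.seed(42)
  vocab <- c("ba", "ce", "di", "fo", "gu")
  for (rep in 1:60) {
    stems <- sample(vocab, sample(4:14, 1L), replace = TRUE)
    # random lexicon of 1-3 token entries over the same vocabulary
    entries <- unique(replicate(6, paste(
      sample(vocab, sample(1:3, 1L), replace = TRUE), collapse = " ")))
    corpus <- tibble::tibble(
      doc_id = "d", text = paste(stems, collapse = " "))
    corpus <- prepare_corpus(corpus)
    lexicon <- tibble::tibble(
      entry_stem = entries,
      n_tokens = lengths(strsplit(entries, " ", fixed = TRUE)),
      term_ids = purrr::map(entries, ~"T")
    )
    got <- annotate_corpus(corpus, lexicon)$entry_stem
    want <- annotate_oracle(corpus$stems[[1]], entries)
    expect_equal(got, want)
  }
})

test_that("matches longer than max_len are not formed", {
  corpus <- corpus_from_texts(list(d = "a1 b2 c3 d4 e5"))
  entries <- c("a1 b2 c3 d4 e5", "a1 b2")
  lexicon <- tibble::tibble(
    entry_stem = entries,
    n_tokens = c(5L, 2L),
    term_ids = list("T", "T"))
  m <- annotate_corpus(corpus, lexicon, max_len = 4L)
  expect_equal(m$entry_stem, "a1 b2")
})

test_that("filter_short drops short words but keeps acronyms", {
  m <- tibble::tibble(
    doc_id = "d",
    entry_stem = c("of", "go", "dna", "go term", "x"),
    surface = c("of", "Go", "DNA", "GO term", "x"),
    start = 0L, end = 1L, first_token = 1L, last_token = 1L,
    term_ids = list("T", "T", "T", "T", "T")
  )
  kept <- filter_short(m)
  expect_setequal(kept$surface, c("DNA", "GO term"))
})

test_that("pos_filter applies the blocklist and head-token tagging", {
  corpus <- corpus_from_texts(list(d = "degrading cellulose in Tennessee"))
  m <- annotate_corpus(corpus, tibble::tibble(
    entry_stem = c("degrad", "cellulos", "tennesse"),
    n_tokens = 1L,
    term_ids = list("T1", "T2", "T3")))
  out <- pos_filter(m, corpus, blocklist = "Tennessee")
  expect_setequal(out$entry_stem, c("degrad", "cellulos"))
  noun_only <- function(tokens) {
    ifelse(tokens %in% c("cellulose", "Tennessee"), "NOUN", "VERB")
  }
  out <- pos_filter(m, corpus, tagger = noun_only)
  expect_setequal(out$entry_stem, c("cellulos", "tennesse"))
  # a failing tagger skips the stage with a warning instead of erroring
  expect_warning(
    out <- pos_filter(m, corpus, tagger = function(tokens) stop("boom")),
    "tagging stage skipped")
  expect_equal(nrow(out), nrow(m))
})

test_that("build_df_index counts distinct documents per stem", {
  m <- tibble::tibble(
    doc_id = c("A", "A", "B", "C"),
    entry_stem = c("x", "x", "x", "y"))
  idx <- build_df_index(m, n_docs = 10L)
  expect_equal(idx$doc_count[idx$entry_stem == "x"], 2L)
  expect_equal(idx$df[idx$entry_stem == "y"], 0.1)
  expect_equal(attr(idx, "corpus_size"), 10L)
  expect_error(build_df_index(m, n_docs = 2L))
})

test_that("apply_df_threshold keeps stems at or under the count cutoff", {
  m <- tibble::tibble(
    doc_id = c("A", "B", "C", "A", "B", "A"),
    entry_stem = c("tri", "tri", "tri", "bi", "bi", "uni"),
    surface = c("tri", "tri", "tri", "Bi", "bi", "uni"))
  idx <- build_df_index(m, n_docs = 100L)
  # ceiling(0.02 * 100) = 2: "bi" (2 docs) in, "tri" (3 docs) out
  labels <- apply_df_threshold(m, idx, threshold = 0.02)
  expect_setequal(unique(labels$stem), c("bi", "uni"))
  expect_equal(labels$phrase[labels$doc_id == "A" & labels$stem == "bi"],
               "Bi")
  # rarest-first ranking within a document, alphabetical on ties
  a <- labels[labels$doc_id == "A", ]
  expect_equal(a$stem, c("uni", "bi"))
  # t = 100% keeps everything
  expect_setequal(unique(apply_df_threshold(m, idx, 1)$stem),
                  c("uni", "bi", "tri"))
  expect_error(apply_df_threshold(m, idx, 0))
})

test_that("derive_ontology_labels composes pruning through thresholding", {
  corpus <- corpus_from_texts(list(
    A = "Amanita thiersii degrades cellulose in lawns",
    B = "cellulose is common here",
    C = "cellulose again and again"
  ))
  onto <- ontology(
    tibble::tibble(
      term_id = c("K", "K1", "K2", "D", "D1"),
      label = c("kept root", "Amanita thiersii", "cellulose",
                "decoy root", "lawn"),
      synonyms = list(character(), character(), character(), character(),
                      character()),
      source = "toy"),
    tibble::tibble(child = c("K1", "K2", "D1"), parent = c("K", "K", "D"))
  )
  labels <- derive_ontology_labels(corpus, onto, keep_roots = list(toy = "K"),
                                   threshold = 0.34)
  # N = 3, ceiling(0.34 * 3) = 2 > 1: cellulose (3 docs) out,
  # amanita thiersii (1 doc) in; "lawn" sits in the pruned decoy branch
  expect_equal(labels$stem, "amanita thiersii")
  expect_equal(labels$source, "ontology")
  matches <- attr(labels, "matches")
  expect_false("lawn" %in% matches$entry_stem)
  expect_s3_class(attr(labels, "df_index"), "df_index")
})
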