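test_that("match_keywords requires full stemmed phrase equality", {
  labels <- c("evolution of symbiosis", "genome", "sorghum")
  expect_setequal(match_keywords(c("genomes", "Sorghum", "maize"), labels),
                  c("genom", "sorghum"))
  # a unigram never gets partial credit against a multiword label
  expect_equal(match_keywords("evolution", labels), character())
  expect_equal(match_keywords("evolution of symbiosis", labels),
               "evolut of symbiosi")
  # duplicates collapse on both sides
  expect_length(match_keywords(c("genome", "genomes"),
                               c("genome", "genomic")), 1L)
})

test_that("f1_score is the harmonic mean with the 0/0 convention", {
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(1, 0), 0)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(c(0.2, 0), c(1, 0)), c(1 / 3, 0))
})

test_that("prf computes the three scores and rejects bad counts", {
  out <- prf(2L, 5L, 3L)
  expect_equal(out$precision, 0.4)
  expect_equal(out$recall, 2 / 3)
  expect_equal(out$f1, 0.5)
  expect_error(prf(4L, 3L, 5L))
  expect_error(prf(1L, 0L, 5L))
})

eval_fixture <- function() {
  labels <- tibble::tibble(
    doc_id = c(rep("d1", 3), "d2"),
    stem = c("genom", "sorghum", "rice", "alpha"))
  keywords <- tibble::tibble(
    doc_id = c(rep("d1", 5), rep("d2", 2)),
    rank = c(1:5, 1:2),
    phrase = c("genome", "maize", "sorghum", "wheat", "barley",
               "alpha", "beta"))
  list(labels = labels, keywords = keywords)
}

test_that("evaluate_corpus macro-averages per-document scores", {
  fx <- eval_fixture()
  ev <- evaluate_corpus(fx$labels, fx$keywords, n_values = 5L)
  d1 <- ev$per_doc[ev$per_doc$doc_id == "d1", ]
  expect_equal(d1$n_matched, 2L)
  expect_equal(d1$precision, 0.4)
  expect_equal(d1$recall, 2 / 3)
  d2 <- ev$per_doc[ev$per_doc$doc_id == "d2", ]
  expect_equal(d2$precision, 0.5)
  expect_equal(d2$recall, 1)
  expect_equal(ev$aggregate$precision, mean(c(0.4, 0.5)))
  expect_equal(ev$aggregate$recall, mean(c(2 / 3, 1)))
  expect_equal(ev$aggregate$f1, mean(c(0.5, 2 / 3)))
  expect_equal(ev$n_docs_scored, 2L)
})

test_that("the micro average pools counts before dividing", {
  fx <- eval_fixture()
  ev <- evaluate_corpus(fx$labels, fx$keywords, n_values = 5L,
                        average = "micro")
  expect_equal(ev$aggregate$precision, 3 / 7)
  expect_equal(ev$aggregate$recall, 3 / 4)
  expect_equal(ev$aggregate$f1, f1_score(3 / 7, 3 / 4))
})

test_that("top-N truncation happens before stemming and matching", {
  labels <- tibble::tibble(doc_id = "d", stem = c("genom", "sorghum"))
  keywords <- tibble::tibble(doc_id = "d", rank = 1:3,
                             phrase = c("maize", "genome", "sorghum"))
  ev <- evaluate_corpus(labels, keywords, n_values = c(2L, 3L))
  expect_equal(ev$per_doc$n_matched[ev$per_doc$n == 2L], 1L)
  expect_equal(ev$per_doc$n_matched[ev$per_doc$n == 3L], 2L)
})

test_that("documents lacking labels or keywords are skipped with reasons", {
  labels <- tibble::tibble(doc_id = c("d1", "d3"),
                           stem = c("genom", "orphan"))
  keywords <- tibble::tibble(doc_id = c("d1", "d2"), rank = 1L,
                             phrase = c("genome", "noise"))
  ev <- evaluate_corpus(labels, keywords, n_values = 5L)
  expect_equal(ev$n_docs_scored, 1L)
  expect_setequal(ev$skipped$doc_id, c("d2", "d3"))
  expect_equal(ev$skipped$reason[ev$skipped$doc_id == "d3"],
               "no extracted keywords")
  expect_error(
    evaluate_corpus(labels[labels$doc_id == "d3", ],
                    keywords[keywords$doc_id == "d2", ]),
    "no document has both")
})

test_that("keyphrase_eval methods behave broom-like", {
  fx <- eval_fixture()
  ev <- evaluate_corpus(fx$labels, fx$keywords, n_values = c(5L, 10L))
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4L)
  gl <- glance(ev)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("f1_at_5", "f1_at_10", "n_docs_scored") %in% names(gl)))
  expect_s3_class(autoplot(ev), "ggplot")
  expect_output(print(ev), "keyphrase_eval")
})

test_that("grid_search enumerates the full Cartesian product", {
  corpus <- corpus_from_texts(list(
    A = "sorghum genome sorghum genome diversity",
    B = "amanita thiersii amanita cellulose"))
  labels <- tibble::tibble(
    doc_id = c("A", "A", "B"),
    stem = c("sorghum genom", "divers", "amanita"))
  axes <- list(ngram = 1:2, window = 1L,
               dedup_method = c("levenshtein", "jaro_winkler"),
               dedup_threshold = c(0.7, 0.9))
  grid <- grid_search(corpus, labels, axes = axes, n_values = c(5L, 10L))
  expect_equal(grid$n_combinations, 8L)
  expect_equal(nrow(grid$table), 16L)
  counts <- table(grid$table$combo_id, grid$table$n)
  expect_true(all(counts == 1L))
  # combos are in lexicographic order on (ngram, window, method, threshold)
  expect_equal(grid$table$ngram[grid$table$combo_id == 1L][1], 1L)
  expect_equal(grid$table$dedup_threshold[grid$table$combo_id == 2L][1], 0.9)
  # the bigram label is only reachable at ngram = 2
  best5 <- grid$best[grid$best$n == 5L, ]
  expect_equal(best5$ngram, 2L)
  # ties resolve to the lexicographically smallest combo, all winners listed
  expect_equal(best5$combo_id, min(best5$tied[[1]]$combo_id))
  expect_true(all(best5$tied[[1]]$f1 == best5$f1))
})

test_that("keyphrase_grid methods and writers work", {
  dir <- withr::local_tempdir()
  corpus <- corpus_from_texts(list(A = "sorghum genome diversity"))
  labels <- tibble::tibble(doc_id = "A", stem = "sorghum")
  axes <- list(ngram = 1:2, window = 1L, dedup_method = "levenshtein",
               dedup_threshold = 0.9)
  grid <- grid_search(corpus, labels, axes = axes, n_values = 5L)
  expect_equal(nrow(tidy(grid)), 2L)
  gl <- glance(grid)
  expect_true(all(c("n_tied", "n_combinations") %in% names(gl)))
  expect_s3_class(autoplot(grid), "ggplot")
  write_grid_csv(grid, file.path(dir, "grid.csv"))
  back <- readr::read_csv(file.path(dir, "grid.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(grid$table))
  ev <- evaluate_corpus(labels,
                        tibble::tibble(doc_id = "A", rank = 1L,
                                       phrase = "sorghum"))
  write_eval_json(ev, file.path(dir, "eval.json"))
  parsed <- jsonlite::fromJSON(file.path(dir, "eval.json"))
  expect_equal(parsed$aggregate$precision, c(1, 1, 1))
})
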