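test_that("clean_text removes URLs, citations and standalone numbers", {
  raw <- "We sequenced 12 samples (Smith et al., 2019); see https://a.b/c"
  expect_equal(clean_text(raw), "We sequenced samples see")
  expect_equal(clean_text("results [3] and [1, 4-6] agree"),
               "results and agree")
  expect_equal(clean_text("the C4 photosynthesis pathway"),
               "the C4 photosynthesis pathway")
  expect_equal(clean_text("iron(III)-reducing micro-organisms"),
               "iron III reducing micro organisms")
})

test_that("clean_text is idempotent, total, and preserves case", {
  raw <- c("Genome-wide survey (Jones et al.) of 300 isolates.",
           "", "plain words already clean", "[12]  www.example.org/x")
  once <- clean_text(raw)
  expect_equal(clean_text(once), once)
  expect_length(once, length(raw))
  expect_match(clean_text("Sorghum Diversity"), "Sorghum")
})

test_that("cleaning rules can be switched off individually", {
  rules <- cleaning_rules(remove_numbers = FALSE)
  expect_equal(clean_text("take 12 samples", rules), "take 12 samples")
  rules <- cleaning_rules(remove_urls = FALSE, remove_punctuation = FALSE)
  expect_match(clean_text("see https://a.b/c", rules), "https://a.b/c",
               fixed = TRUE)
})

test_that("tokenize reports 0-based half-open spans that recover tokens", {
  text <- "comparative genomics of C4 grasses"
  tok <- tokenize(text)
  expect_equal(tok$token,
               c("comparative", "genomics", "of", "C4", "grasses"))
  recovered <- substr(rep(text, nrow(tok)), tok$start + 1L, tok$end)
  expect_equal(recovered, tok$token)
  expect_equal(tok$start[[1]], 0L)
  expect_equal(nrow(tokenize("")), 0L)
  expect_equal(nrow(tokenize("   ")), 0L)
})

test_that("prepare_corpus attaches aligned tokens and stems", {
  corpus <- corpus_from_texts(list(
    d1 = "Sequencing halorespiring bacteria.",
    d2 = ""
  ))
  expect_equal(names(corpus$stems[[1]]), NULL)
  expect_equal(corpus$stems[[1]], c("sequenc", "halorespir", "bacteria"))
  expect_equal(nrow(corpus$tokens[[1]]), 3L)
  expect_equal(length(corpus$stems[[2]]), 0L)
})

test_that("document tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "corpus.csv")
  corpus <- tibble::tibble(
    doc_id = c("A", "B"),
    title = c("Sorghum genome", "Amanita thiersii"),
    description = c("diversity of grasses", ""),
    text = c("Sorghum genome diversity of grasses", "Amanita thiersii")
  )
  write_document_table(corpus, path)
  back <- read_document_table(path, semantic_fields = c("title",
                                                        "description"))
  expect_equal(back$doc_id, corpus$doc_id)
  expect_equal(back$text, corpus$text)
})

test_that("read_document_table joins only non-empty fields in order", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "corpus.csv")
  readr::write_csv(tibble::tibble(
    id = c("A", "B"),
    title = c("first title", ""),
    `summary of work` = c("the summary", "only summary")
  ), path)
  out <- read_document_table(
    path, semantic_fields = c("title", "summary of work"))
  expect_equal(out$text, c("first title the summary", "only summary"))
})

test_that("read_document_table fails on duplicate or missing IDs", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.csv")
  readr::write_csv(tibble::tibble(id = c("A", "A"), title = c("x", "y")),
                   dup)
  expect_error(read_document_table(dup, semantic_fields = "title"),
               "duplicate doc_id")
  noid <- file.path(dir, "noid.csv")
  readr::write_csv(tibble::tibble(title = "x"), noid)
  expect_error(read_document_table(noid, semantic_fields = "title"),
               "id column")
})

test_that("read_document_table warns on empty corpora and empty documents", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.csv")
  readr::write_csv(tibble::tibble(id = character(), title = character()),
                   empty)
  expect_warning(read_document_table(empty, semantic_fields = "title"),
                 "zero rows")
  blank <- file.path(dir, "blank.csv")
  readr::write_csv(tibble::tibble(id = c("A", "B"), title = c("x", "")),
                   blank)
  expect_warning(read_document_table(blank, semantic_fields = "title"),
                 "no semantic text")
})

test_that("keyword records round-trip through JSON", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "records.json")
  records <- dplyr::bind_rows(
    record_row("P1", c("A", "B"), wos = c("sorghum genome"),
               mesh = c("Poaceae")),
    record_row("P2", character(), pubmed = "cellulose degradation")
  )
  write_keyword_records(records, path)
  back <- read_keyword_records(path)
  expect_equal(back$record_id, c("P1", "P2"))
  expect_equal(back$linked_doc_ids[[1]], c("A", "B"))
  expect_equal(back$keywords[[1]]$wos_author, "sorghum genome")
  expect_equal(back$keywords[[1]]$mesh, "Poaceae")
  report <- attr(back, "load_report")
  expect_equal(report$n_records, 2L)
  expect_equal(report$n_unlinked, 1L)
  expect_equal(report$n_skipped, 0L)
})

test_that("records with unknown sources are rejected and reported", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "records.json")
  jsonlite::write_json(list(
    list(record_id = "P1", links = list("A"),
         keywords = list(wos_author = list("ok"))),
    list(record_id = "P2", links = list("A"),
         keywords = list(scopus = list("nope"))),
    list(links = list("B"), keywords = list(mesh = list("orphan")))
  ), path, auto_unbox = TRUE)
  back <- read_keyword_records(path)
  expect_equal(back$record_id, "P1")
  report <- attr(back, "load_report")
  expect_equal(report$n_skipped, 2L)
  expect_true(any(grepl("unknown source", report$messages)))
})

test_that("keyword records load from the CSV dialect", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "records.csv")
  readr::write_csv(tibble::tibble(
    record_id = c("P1", "P1", "P2", "P3"),
    doc_ids = c("A;B", "A;B", "C", "C"),
    source = c("wos_author", "mesh", "pubmed_author", "scopus"),
    keyword = c("sorghum", "Poaceae", "genome", "bad")
  ), path)
  back <- read_keyword_records(path)
  expect_equal(sort(back$record_id), c("P1", "P2"))
  p1 <- back[back$record_id == "P1", ]
  expect_equal(p1$linked_doc_ids[[1]], c("A", "B"))
  expect_equal(p1$keywords[[1]]$wos_author, "sorghum")
  expect_equal(attr(back, "load_report")$n_skipped, 1L)
})
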