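# Publication-derived labels: link documents to keyword records through
# shared IDs, pool the records' keywords across sources, and keep only
# keywords whose stemmed form actually occurs in the document text.

# contiguous stem-subsequence test
.contains_stem_seq <- function(doc_stems, phrase_stems) {
  k <- length(phrase_stems)
  n <- length(doc_stems)
  if (k == 0L || k > n) return(FALSE)
  if (k == 1L) return(phrase_stems %in% doc_stems)
  starts <- which(doc_stems == phrase_stems[[1L]])
  for (s in starts) {
    if (s + k - 1L <= n &&
        all(doc_stems[s:(s + k - 1L)] == phrase_stems)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Link documents to keyword records by shared ID
#'
#' A document is linked to every record whose `linked_doc_ids` contains
#' its `doc_id`; links are many-to-many. Links pointing at unknown
#' documents are ignored and counted.
#'
#' @param corpus Corpus tibble with unique `doc_id`.
#' @param records Keyword-record tibble (see [read_keyword_records()]).
#' @return A tibble with one row per (doc_id, record_id) link, carrying a
#'   `"link_report"` attribute: `n_docs_linked`, `n_records_used`,
#'   `n_dangling`, and the dangling IDs.
#' @export
link_by_id <- function(corpus, records) {
  stopifnot(!anyDuplicated(corpus$doc_id))
  long <- tidyr::unnest(
    tibble::tibble(record_id = records$record_id,
                   doc_id = records$linked_doc_ids),
    "doc_id"
  )
  known <- long$doc_id %in% corpus$doc_id
  dangling <- unique(long$doc_id[!known])
  links <- dplyr::arrange(long[known, c("doc_id", "record_id")],
                          .data$doc_id, .data$record_id)
  attr(links, "link_report") <- list(
    n_docs_linked = dplyr::n_distinct(links$doc_id),
    n_records_used = dplyr::n_distinct(links$record_id),
    n_dangling = length(dangling),
    dangling = dangling
  )
  links
}

#' Pool keywords across records and sources
#'
#' Takes the union of the requested per-source keyword lists over a set of
#' records, deduplicated case-insensitively on the stemmed phrase. The
#' first-seen surface form represents each stem; order is deterministic
#' (record order, then source order, then list order).
#'
#' @param records Keyword-record tibble.
#' @param sources Subset of [keyword_sources()] to pool.
#' @return A tibble with `phrase`, `stem`, `source` (source of the first
#'   occurrence).
#' @export
pool_keywords <- function(records, sources = keyword_sources()) {
  stopifnot(all(sources %in% keyword_sources()))
  if (nrow(records) == 0L) {
    return(tibble::tibble(phrase = character(), stem = character(),
                          source = character()))
  }
  pooled <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    kw <- records$keywords[[i]]
    purrr::map_dfr(sources, function(s) {
      phrases <- kw[[s]] %||% character()
      tibble::tibble(phrase = phrases, source = s)
    })
  })
  if (nrow(pooled) == 0L) {
    return(tibble::tibble(phrase = character(), stem = character(),
                          source = character()))
  }
  pooled$stem <- stem_phrase(pooled$phrase)
  pooled <- pooled[nzchar(pooled$stem), ]
  pooled <- pooled[!duplicated(pooled$stem), c("phrase", "stem", "source")]
  tibble::as_tibble(pooled)
}

#' Keep only keywords present in the document text
#'
#' A phrase survives iff its stemmed token sequence occurs contiguously in
#' the document's stem sequence, so morphological variants still count
#' ("genome" matches a document containing "genomes") but a bigram must
#' appear as a bigram.
#'
#' @param phrases Tibble with `phrase` and `stem` columns (e.g. from
#'   [pool_keywords()]), or a character vector of phrases.
#' @param doc_stems Character vector: the document's per-token stems.
#' @return The surviving rows, as publication-source labels: a tibble with
#'   `phrase`, `stem`, `source = "publication"`.
#' @export
filter_keywords_in_text <- function(phrases, doc_stems) {
  if (is.character(phrases)) {
    phrases <- tibble::tibble(phrase = phrases, stem = stem_phrase(phrases))
  }
  if (nrow(phrases) == 0L) {
    return(tibble::tibble(phrase = character(), stem = character(),
                          source = character()))
  }
  keep <- vapply(phrases$stem, function(s) {
    .contains_stem_seq(doc_stems, strsplit(s, " ", fixed = TRUE)[[1L]])
  }, logical(1), USE.NAMES = FALSE)
  out <- phrases[keep, c("phrase", "stem")]
  out$source <- "publication"
  tibble::as_tibble(out)
}

#' Derive publication labels for a whole corpus
#'
#' For every linked document: pool the linked records' keywords across the
#' requested sources, drop those absent from the document text, and
#' deduplicate on the stemmed phrase. Linked documents that end up with no
#' labels are flagged in the `"empty_docs"` attribute (they are not rows
#' of the result).
#'
#' @param corpus Prepared corpus (see [prepare_corpus()]; needs the
#'   `stems` list-column).
#' @param records Keyword-record tibble.
#' @param sources Subset of [keyword_sources()].
#' @return Label tibble: `doc_id`, `phrase`, `stem`, `source`
#'   (`"publication"`), `score` (`NA`; scores belong to ontology labels).
#' @export
derive_publication_labels <- function(corpus, records,
                                      sources = keyword_sources()) {
  stopifnot("stems" %in% names(corpus))
  links <- link_by_id(corpus, records)
  empty_docs <- character()
  out <- purrr::map_dfr(unique(links$doc_id), function(d) {
    recs <- records[records$record_id %in%
                      links$record_id[links$doc_id == d], ]
    pooled <- pool_keywords(recs, sources)
    kept <- filter_keywords_in_text(
      pooled, corpus$stems[[match(d, corpus$doc_id)]])
    if (nrow(kept) == 0L) {
      empty_docs <<- c(empty_docs, d)
      return(NULL)
    }
    tibble::tibble(doc_id = d, phrase = kept$phrase, stem = kept$stem,
                   source = "publication", score = NA_real_)
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(doc_id = character(), phrase = character(),
                          stem = character(), source = character(),
                          score = double())
  }
  if (length(empty_docs) > 0L) {
    rlang::inform(sprintf(
      "%d linked document(s) retained no keywords: %s", length(empty_docs),
      paste(utils::head(empty_docs, 5L), collapse = ", ")))
  }
  attr(out, "empty_docs") <- empty_docs
  attr(out, "link_report") <- attr(links, "link_report")
  out
}

#' Write a label table as TSV and its link report as JSON
#'
#' @param labels Label tibble (`doc_id`, `phrase`, `stem`, `source`,
#'   optional `score`).
#' @param path Output `.tsv` path; a `"link_report"` attribute, if
#'   present, is written next to it as `<path>.report.json`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(tibble::as_tibble(labels), path, progress = FALSE)
  report <- attr(labels, "link_report")
  if (!is.null(report)) {
    jsonlite::write_json(report, paste0(path, ".report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
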