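# Reading the document corpus and keyword-record files, and turning raw
# field text into the cleaned / tokenized / stemmed views every later
# stage works from.

#' Default semantic fields of a proposal table
#'
#' The eight free-text fields of a research-proposal record that carry
#' semantic content (as opposed to administrative metadata), in the order
#' they are joined into each document's text.
#'
#' @return Character vector of eight field names.
#' @export
default_semantic_fields <- function() {
  c("title", "description", "justification", "community interest",
    "summary of work", "sample preparation", "utilization", "DOE mission")
}

#' Registered keyword-record sources
#'
#' @return Character vector of the recognised per-source keyword list
#'   names: Web of Science author keywords, PubMed author keywords, and
#'   MeSH terms.
#' @export
keyword_sources <- function() {
  c("wos_author", "pubmed_author", "mesh")
}

#' Text-cleaning rule set
#'
#' Controls which regex-based removals [clean_text()] applies. All four
#' classes are on by default: URLs, citations (parenthetical author-year
#' and bracketed numeric), standalone numbers, and punctuation (hyphens
#' and slashes become token separators).
#'
#' @param remove_urls,remove_citations,remove_numbers,remove_punctuation
#'   Logical flags, one per rule class.
#' @return A `cleaning_rules` list.
#' @export
cleaning_rules <- function(remove_urls = TRUE, remove_citations = TRUE,
                           remove_numbers = TRUE, remove_punctuation = TRUE) {
  structure(
    list(remove_urls = remove_urls, remove_citations = remove_citations,
         remove_numbers = remove_numbers,
         remove_punctuation = remove_punctuation),
    class = "cleaning_rules"
  )
}

#' Clean raw text for NLP ingestion
#'
#' Applies regex-based removals (URLs, citations, standalone numbers,
#' punctuation) and collapses whitespace. Case is preserved; lowercasing
#' happens later, at stemming. Alphanumeric tokens such as "C4" are kept:
#' only purely numeric tokens are treated as numbers. The function is
#' total and idempotent.
#'
#' @param text Character vector.
#' @param rules A [cleaning_rules()] object.
#' @return Character vector of cleaned text, same length as `text`.
#' @examples
#' clean_text("We sequenced 12 samples (Smith et al., 2019); see https://a.b/c")
#' @export
clean_text <- function(text, rules = cleaning_rules()) {
  stopifnot(is.character(text), inherits(rules, "cleaning_rules"))
  out <- text
  if (rules$remove_urls) {
    out <- stringr::str_replace_all(out, "(?:https?://|www\\.)\\S+", " ")
  }
  if (rules$remove_citations) {
    # parenthesised spans carrying an "et al." or a year
    out <- stringr::str_replace_all(
      out, stringr::regex("\\([^()]*(?:et\\s+al\\.?|\\b(?:1[6-9]|20)[0-9]{2}\\b)[^()]*\\)"),
      " "
    )
    # bracketed numeric citations like [3] or [1, 4-6]
    out <- stringr::str_replace_all(
      out, "\\[[0-9]+(?:\\s*[,;–-]\\s*[0-9]+)*\\]", " "
    )
  }
  if (rules$remove_numbers) {
    out <- stringr::str_replace_all(
      out, stringr::regex("(?<![[:alnum:]])[0-9]+(?:\\.[0-9]+)?(?![[:alnum:]])"),
      " "
    )
  }
  if (rules$remove_punctuation) {
    out <- stringr::str_replace_all(out, "[^[:alnum:][:space:]]+", " ")
  }
  stringr::str_squish(out)
}

#' Tokenize text with character spans
#'
#' Splits text into alphanumeric tokens and records each token's
#' character span into the input string, 0-based and half-open, so
#' `substr(text, start + 1, end)` recovers the token.
#'
#' @param text A single string.
#' @return A tibble with columns `token`, `start`, `end`.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer()))
  }
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer()))
  }
  len <- attr(m, "match.length")
  tibble::tibble(
    token = substring(text, m, m + len - 1L),
    start = as.integer(m) - 1L,
    end = as.integer(m) + as.integer(len) - 1L
  )
}

#' Tokenize and stem a text string
#'
#' @param text A single string (typically already cleaned).
#' @return A list with `tokens` (tibble from [tokenize()]) and `stems`
#'   (character vector of the same length: lowercased Porter stems).
#' @export
tokenize_and_stem <- function(text) {
  tokens <- tokenize(text)
  list(tokens = tokens, stems = porter_stem(tokens$token))
}

#' Read a document corpus from CSV
#'
#' One row per document. The named semantic fields are joined (non-empty
#' ones, in the given order, with single spaces) into each document's
#' `text`. Fields missing from the file, or empty in a row, contribute
#' nothing.
#'
#' @param path CSV file with a header.
#' @param id_field Name of the document-identifier column.
#' @param semantic_fields Ordered character vector of free-text columns to
#'   join; defaults to the eight of [default_semantic_fields()].
#' @return A tibble with `doc_id`, one column per semantic field, and
#'   `text`. Documents keep file order.
#' @export
read_document_table <- function(path, id_field = "id",
                                semantic_fields = default_semantic_fields()) {
  stopifnot(length(semantic_fields) >= 1L)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!id_field %in% names(raw)) {
    rlang::abort(sprintf("id column '%s' not found in %s", id_field, path))
  }
  if (nrow(raw) == 0L) {
    rlang::warn(sprintf("corpus file %s has zero rows", path))
  }
  missing_fields <- setdiff(semantic_fields, names(raw))
  for (f in missing_fields) raw[[f]] <- ""
  doc_id <- raw[[id_field]]
  dup <- unique(doc_id[duplicated(doc_id)])
  if (length(dup) > 0L) {
    rlang::abort(sprintf("duplicate doc_id(s): %s",
                         paste(dup, collapse = ", ")))
  }
  fields <- raw[semantic_fields]
  fields[is.na(fields)] <- ""
  text <- apply(fields, 1L, function(row) {
    paste(row[nzchar(row)], collapse = " ")
  })
  if (length(text) == 0L) text <- character()
  empty <- !nzchar(text)
  if (any(empty)) {
    rlang::warn(sprintf(
      "%d document(s) have no semantic text: %s", sum(empty),
      paste(utils::head(doc_id[empty], 5L), collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(fields)
  out <- dplyr::bind_cols(tibble::tibble(doc_id = doc_id), out)
  out$text <- unname(text)
  out
}

#' Write a document corpus to CSV
#'
#' Inverse of [read_document_table()]: writes `doc_id` (as column `id`)
#' plus every semantic-field column, so a written corpus re-reads
#' identically.
#'
#' @param corpus Tibble from [read_document_table()] or the synthetic
#'   generator.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_document_table <- function(corpus, path) {
  keep <- setdiff(names(corpus), c("text", "clean_text", "tokens", "stems"))
  out <- corpus[keep]
  names(out)[names(out) == "doc_id"] <- "id"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Attach cleaned, tokenized and stemmed views to a corpus
#'
#' Adds `clean_text`, a `tokens` list-column (tibbles with spans into
#' `clean_text`) and a `stems` list-column (per-token Porter stems) to a
#' corpus tibble.
#'
#' @param corpus Tibble with `doc_id` and `text`.
#' @param rules A [cleaning_rules()] object.
#' @return The corpus tibble with the three derived columns.
#' @export
prepare_corpus <- function(corpus, rules = cleaning_rules()) {
  stopifnot(all(c("doc_id", "text") %in% names(corpus)))
  corpus$clean_text <- clean_text(corpus$text, rules)
  ts <- purrr::map(corpus$clean_text, tokenize_and_stem)
  corpus$tokens <- purrr::map(ts, "tokens")
  corpus$stems <- purrr::map(ts, "stems")
  corpus
}

.normalize_record <- function(rec, origin, report) {
  record_id <- rec$record_id %||% rec$id
  if (is.null(record_id) || !nzchar(record_id)) {
    report$skipped <- report$skipped + 1L
    report$messages <- c(report$messages,
                         sprintf("%s: record without an id skipped", origin))
    return(list(rec = NULL, report = report))
  }
  links <- as.character(unlist(rec$links %||% rec$linked_doc_ids %||% list()))
  kw <- rec$keywords %||% rec[intersect(names(rec), keyword_sources())]
  unknown <- setdiff(names(kw), keyword_sources())
  if (length(unknown) > 0L) {
    report$skipped <- report$skipped + 1L
    report$messages <- c(report$messages, sprintf(
      "%s: record '%s' rejected, unknown source(s): %s",
      origin, record_id, paste(unknown, collapse = ", ")))
    return(list(rec = NULL, report = report))
  }
  keywords <- stats::setNames(
    lapply(keyword_sources(), function(s) {
      v <- as.character(unlist(kw[[s]] %||% character()))
      v[nzchar(v)]
    }),
    keyword_sources()
  )
  list(
    rec = tibble::tibble(
      record_id = as.character(record_id),
      linked_doc_ids = list(links),
      keywords = list(keywords)
    ),
    report = report
  )
}

#' Read keyword records for labeled artifacts
#'
#' Loads the offline record files standing in for publication metadata
#' pulled from Web of Science / PubMed. Two encodings are accepted:
#' * JSON: an array of objects with `record_id` (or `id`), `links` (array
#'   of document IDs) and per-source keyword arrays, either nested under
#'   `keywords` or as top-level keys (`wos_author`, `pubmed_author`,
#'   `mesh`).
#' * CSV: one row per record-source-keyword, with columns `record_id`,
#'   `doc_ids` (semicolon-separated), `source`, `keyword`.
#'
#' Keywords are kept verbatim; no normalization happens at read time.
#' Records naming an unknown source are rejected; malformed rows are
#' skipped. Both are counted in the load report attached as the
#' `"load_report"` attribute (fields `n_records`, `n_skipped`,
#' `n_unlinked`, `messages`).
#'
#' @param path A `.json` or `.csv` file.
#' @return A tibble with `record_id`, `linked_doc_ids` (list-column of
#'   character vectors) and `keywords` (list-column of named lists,
#'   source -> character vector).
#' @export
read_keyword_records <- function(path) {
  report <- list(skipped = 0L, messages = character())
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- list()
    for (rec in raw) {
      res <- .normalize_record(rec, path, report)
      report <- res$report
      if (!is.null(res$rec)) rows[[length(rows) + 1L]] <- res$rec
    }
    records <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(record_id = character(), linked_doc_ids = list(),
                     keywords = list())
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    needed <- c("record_id", "doc_ids", "source", "keyword")
    if (!all(needed %in% names(raw))) {
      rlang::abort(sprintf(
        "keyword-record CSV %s must have columns %s", path,
        paste(needed, collapse = ", ")))
    }
    bad_source <- !is.na(raw$source) & !raw$source %in% keyword_sources()
    if (any(bad_source)) {
      report$skipped <- report$skipped + sum(bad_source)
      report$messages <- c(report$messages, sprintf(
        "%s: %d row(s) rejected, unknown source(s): %s", path,
        sum(bad_source),
        paste(unique(raw$source[bad_source]), collapse = ", ")))
      raw <- raw[!bad_source, ]
    }
    malformed <- is.na(raw$record_id) | is.na(raw$source) | is.na(raw$keyword)
    if (any(malformed)) {
      report$skipped <- report$skipped + sum(malformed)
      report$messages <- c(report$messages, sprintf(
        "%s: %d malformed row(s) skipped", path, sum(malformed)))
      raw <- raw[!malformed, ]
    }
    ids <- unique(raw$record_id)
    rows <- lapply(ids, function(rid) {
      sub <- raw[raw$record_id == rid, ]
      links <- unique(unlist(strsplit(sub$doc_ids[!is.na(sub$doc_ids)], ";",
                                      fixed = TRUE)))
      links <- links[nzchar(links)]
      keywords <- stats::setNames(
        lapply(keyword_sources(), function(s) sub$keyword[sub$source == s]),
        keyword_sources()
      )
      tibble::tibble(record_id = rid, linked_doc_ids = list(links),
                     keywords = list(keywords))
    })
    records <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(record_id = character(), linked_doc_ids = list(),
                     keywords = list())
  }
  n_unlinked <- sum(purrr::map_int(records$linked_doc_ids, length) == 0L)
  attr(records, "load_report") <- list(
    n_records = nrow(records), n_skipped = report$skipped,
    n_unlinked = n_unlinked, messages = report$messages
  )
  records
}

#' Write keyword records as JSON
#'
#' @param records Tibble from [read_keyword_records()] or the synthetic
#'   generator.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_keyword_records <- function(records, path) {
  out <- purrr::pmap(records, function(record_id, linked_doc_ids, keywords,
                                       ...) {
    list(record_id = record_id, links = as.list(linked_doc_ids),
         keywords = purrr::map(keywords, as.list))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
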