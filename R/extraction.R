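# Machine keyphrase extraction behind a pluggable adapter interface. The
# statistical extractor used in production settings (e.g. YAKE) is an
# external tool; its output is injected through the adapter registry or
# read back from JSON. A deterministic frequency-based extractor ships
# built in so the evaluation and tuning machinery is testable with no
# third-party dependency.

#' Extractor hyperparameters
#'
#' The tuning surface of an unsupervised keyphrase extractor: longest
#' phrase length, context window size, deduplication metric and threshold,
#' and the number of keyphrases returned. `dedup_method` and
#' `dedup_threshold` are passed through to external adapters; the built-in
#' frequency extractor ignores the window and deduplicates on stem
#' equality only.
#'
#' @param ngram Longest phrase length in tokens (grid values 1-3).
#' @param window Context window size (grid values 1-3).
#' @param dedup_method One of `"levenshtein"`, `"sequence_matcher"`,
#'   `"jaro_winkler"`.
#' @param dedup_threshold Allowed similarity between candidates, in (0,1).
#' @param top_n Number of keyphrases to return (evaluation uses 5/10/20).
#' @return An `extractor_params` list.
#' @export
extractor_params <- function(ngram = 1L, window = 2L,
                             dedup_method = c("levenshtein",
                                              "sequence_matcher",
                                              "jaro_winkler"),
                             dedup_threshold = 0.9, top_n = 20L) {
  dedup_method <- match.arg(dedup_method)
  stopifnot(ngram >= 1L, window >= 1L,
            dedup_threshold > 0, dedup_threshold < 1, top_n >= 1L)
  structure(
    list(ngram = as.integer(ngram), window = as.integer(window),
         dedup_method = dedup_method,
         dedup_threshold = dedup_threshold, top_n = as.integer(top_n)),
    class = "extractor_params"
  )
}

#' The paper-style tuning grid axes
#'
#' Default grid: ngram 1-3, window 1-3, three deduplication metrics, five
#' thresholds - 135 combinations.
#'
#' @return Named list of axis values for [grid_search()].
#' @export
default_grid_axes <- function() {
  list(
    ngram = 1:3,
    window = 1:3,
    dedup_method = c("levenshtein", "sequence_matcher", "jaro_winkler"),
    dedup_threshold = c(0.6, 0.7, 0.8, 0.9, 0.95)
  )
}

.extractor_registry <- new.env(parent = emptyenv())

#' Register a keyphrase-extractor adapter
#'
#' @param name Adapter name.
#' @param fn Function `(clean_text, params)` returning a ranked character
#'   vector of lowercased phrases, best first.
#' @return `name`, invisibly.
#' @export
register_extractor <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .extractor_registry)
  invisible(name)
}

#' List registered extractor adapters
#'
#' @return Character vector of adapter names.
#' @export
list_extractors <- function() {
  sort(ls(.extractor_registry))
}

.get_extractor <- function(name) {
  fn <- .extractor_registry[[name]]
  if (is.null(fn)) {
    rlang::abort(sprintf(
      "no extractor adapter named '%s' (registered: %s)", name,
      paste(list_extractors(), collapse = ", ")))
  }
  fn
}

#' English stopword list
#'
#' A compact packaged list of English function words, extendable with a
#' user-supplied domain list (discussion-worthy because ontology-based
#' labeling is sensitive to the stoplist).
#'
#' @param extra Additional stopwords to append.
#' @return Character vector of lowercase stopwords.
#' @export
stopwords_en <- function(extra = character()) {
  base <- c(
    "a", "about", "above", "after", "again", "against", "all", "also",
    "am", "an", "and", "any", "are", "as", "at", "be", "because", "been",
    "before", "being", "below", "between", "both", "but", "by", "can",
    "cannot", "could", "did", "do", "does", "doing", "down", "during",
    "each", "few", "for", "from", "further", "had", "has", "have",
    "having", "he", "her", "here", "hers", "herself", "him", "himself",
    "his", "how", "i", "if", "in", "into", "is", "it", "its", "itself",
    "may", "me", "might", "more", "most", "must", "my", "myself", "no",
    "nor", "not", "of", "off", "on", "once", "only", "or", "other",
    "ought", "our", "ours", "ourselves", "out", "over", "own", "same",
    "shall", "she", "should", "so", "some", "such", "than", "that", "the",
    "their", "theirs", "them", "themselves", "then", "there", "these",
    "they", "this", "those", "through", "to", "too", "under", "until",
    "up", "upon", "us", "very", "was", "we", "were", "what", "when",
    "where", "which", "while", "who", "whom", "why", "will", "with",
    "would", "you", "your", "yours", "yourself", "yourselves"
  )
  unique(c(base, tolower(extra)))
}

# Built-in deterministic extractor: candidate phrases are the n-grams
# (n <= params$ngram) inside maximal runs of non-stopword tokens, scored
# by within-document frequency normalized by phrase length; ties broken
# alphabetically. Duplicates collapsing to one stem are removed, best
# kept.
.frequency_extractor <- function(clean_text, params,
                                 stopwords = stopwords_en()) {
  tokens <- tolower(tokenize(clean_text)$token)
  if (length(tokens) == 0L) return(character())
  keep <- !tokens %in% stopwords
  run_id <- cumsum(!keep)
  runs <- split(tokens[keep], run_id[keep])
  counts <- new.env(parent = emptyenv())
  for (run in runs) {
    L <- length(run)
    for (n in seq_len(min(params$ngram, L))) {
      for (i in seq_len(L - n + 1L)) {
        phrase <- paste(run[i:(i + n - 1L)], collapse = " ")
        counts[[phrase]] <- (counts[[phrase]] %||% 0L) + 1L
      }
    }
  }
  phrases <- ls(counts)
  if (length(phrases) == 0L) return(character())
  freq <- vapply(phrases, function(p) counts[[p]], numeric(1))
  len <- lengths(strsplit(phrases, " ", fixed = TRUE))
  ord <- order(-freq / len, phrases)
  ranked <- phrases[ord]
  ranked <- ranked[!duplicated(stem_phrase(ranked))]
  utils::head(ranked, params$top_n)
}

# adapter registration at load time
.register_builtin_extractors <- function() {
  register_extractor("frequency", function(clean_text, params) {
    .frequency_extractor(clean_text, params)
  })
}

#' Extract ranked keyphrases from one document
#'
#' Runs the named adapter on the document's cleaned text. Results are
#' lowercased, at most `params$top_n` long, best first, and deterministic
#' for a fixed input and parameterization.
#'
#' @param clean_text The document's cleaned text (a single string).
#' @param params An [extractor_params()] object.
#' @param extractor Adapter name; `"frequency"` is built in.
#' @return Ranked character vector of phrases (empty, with a warning, for
#'   empty text).
#' @export
extract_keywords <- function(clean_text, params = extractor_params(),
                             extractor = "frequency") {
  fn <- .get_extractor(extractor)
  if (is.na(clean_text) || !nzchar(clean_text)) {
    rlang::warn("empty document text: no keywords extracted")
    return(character())
  }
  out <- tolower(fn(clean_text, params))
  utils::head(out, params$top_n)
}

#' Extract keyphrases for a whole corpus
#'
#' Per-document extraction with per-document failure isolation: a document
#' whose extraction errors contributes an empty list and is reported in
#' the `"failures"` attribute.
#'
#' @param corpus Prepared corpus (needs `clean_text`).
#' @param params An [extractor_params()] object.
#' @param extractor Adapter name.
#' @return A keyword tibble: `doc_id`, `rank`, `phrase`.
#' @export
batch_extract <- function(corpus, params = extractor_params(),
                          extractor = "frequency") {
  stopifnot(nrow(corpus) > 0L, "clean_text" %in% names(corpus))
  failures <- character()
  out <- purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    phrases <- tryCatch(
      extract_keywords(corpus$clean_text[[i]], params, extractor),
      error = function(e) {
        failures <<- c(failures, sprintf("%s: %s", corpus$doc_id[[i]],
                                         conditionMessage(e)))
        character()
      }
    )
    if (length(phrases) == 0L) return(NULL)
    tibble::tibble(doc_id = corpus$doc_id[[i]],
                   rank = seq_along(phrases), phrase = phrases)
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(doc_id = character(), rank = integer(),
                          phrase = character())
  }
  if (length(failures) > 0L) {
    rlang::warn(sprintf("extraction failed for %d document(s)",
                        length(failures)))
  }
  attr(out, "failures") <- failures
  out
}

#' Read / write keyword lists as JSON
#'
#' The JSON layout is a single object mapping `doc_id` to an ordered array
#' of phrases, so externally produced extractor output (e.g. YAKE run
#' elsewhere) can be injected into evaluation unchanged.
#'
#' @param path JSON file path.
#' @return For `read_keywords_json()`: a keyword tibble (`doc_id`, `rank`,
#'   `phrase`).
#' @export
read_keywords_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- purrr::imap_dfr(raw, function(phrases, d) {
    phrases <- as.character(phrases)
    if (length(phrases) == 0L) return(NULL)
    tibble::tibble(doc_id = d, rank = seq_along(phrases), phrase = phrases)
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(doc_id = character(), rank = integer(),
                          phrase = character())
  }
  out
}

#' @param keywords Keyword tibble (`doc_id`, `rank`, `phrase`).
#' @rdname read_keywords_json
#' @export
write_keywords_json <- function(keywords, path) {
  out <- purrr::map(split(keywords, keywords$doc_id),
                    function(x) as.list(x$phrase[order(x$rank)]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
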