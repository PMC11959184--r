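# Ontology-derived labels: load and merge ontologies, prune to curated
# branches, recognise term mentions in document text by stemmed
# longest-match, filter short/ill-tagged matches, and rank what is left
# by document frequency.

#' Construct an ontology object
#'
#' @param terms Tibble with `term_id`, `label`, `synonyms` (list-column of
#'   character vectors), `source` (source-ontology name).
#' @param edges Tibble with `child`, `parent` (is-a links between term
#'   IDs).
#' @return An `ontology` object (validated: edge endpoints exist, the
#'   graph is acyclic, synonyms deduplicated).
#' @export
ontology <- function(terms, edges) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  dup <- unique(terms$term_id[duplicated(terms$term_id)])
  if (length(dup) > 0L) {
    rlang::abort(sprintf("duplicate term_id(s): %s",
                         paste(dup, collapse = ", ")))
  }
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms$term_id)
  if (length(missing) > 0L) {
    rlang::abort(sprintf("edge endpoint(s) not in terms: %s",
                         paste(missing, collapse = ", ")))
  }
  cyc <- .find_cycle(terms$term_id, edges)
  if (!is.null(cyc)) {
    rlang::abort(sprintf("ontology graph has a cycle: %s",
                         paste(cyc, collapse = " -> ")))
  }
  terms$synonyms <- purrr::map(terms$synonyms, ~ unique(as.character(.x)))
  structure(list(terms = terms, edges = edges), class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology: %d terms, %d is-a edges, sources: %s>\n",
              nrow(x$terms), nrow(x$edges),
              paste(unique(x$terms$source), collapse = ", ")))
  invisible(x)
}

# Kahn's algorithm; returns a cycle path or NULL
.find_cycle <- function(ids, edges) {
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  children <- split(edges$parent, edges$child)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in children[[v]] %||% character()) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk the residual graph to print one cycle
  residual <- names(indeg)[indeg > 0L]
  path <- residual[[1L]]
  repeat {
    nxt <- edges$parent[edges$child == path[[length(path)]] &
                          edges$parent %in% residual][1L]
    if (nxt %in% path) return(c(path[which(path == nxt):length(path)], nxt))
    path <- c(path, nxt)
  }
}

.read_ontology_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("term_id", "label")
  if (!all(needed %in% names(raw))) {
    rlang::abort(sprintf("ontology TSV %s needs columns term_id, label",
                         path))
  }
  src <- if ("source" %in% names(raw)) raw$source else
    rep(tools::file_path_sans_ext(basename(path)), nrow(raw))
  split_col <- function(x) {
    purrr::map(x, function(v) {
      if (is.na(v) || !nzchar(v)) character() else
        strsplit(v, "|", fixed = TRUE)[[1L]]
    })
  }
  synonyms <- if ("synonyms" %in% names(raw)) split_col(raw$synonyms) else
    rep(list(character()), nrow(raw))
  parents <- if ("parents" %in% names(raw)) split_col(raw$parents) else
    rep(list(character()), nrow(raw))
  terms <- tibble::tibble(term_id = raw$term_id, label = raw$label,
                          synonyms = synonyms, source = src)
  edges <- tidyr::unnest(
    tibble::tibble(child = raw$term_id, parent = parents), "parent")
  list(terms = terms, edges = edges)
}

.read_ontology_obograph <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  graphs <- doc$graphs %||% list(doc)
  terms <- list(); edges <- list()
  for (g in graphs) {
    src <- tools::file_path_sans_ext(basename(g$id %||% path))
    for (node in g$nodes %||% list()) {
      syns <- purrr::map_chr(node$meta$synonyms %||% list(),
                             ~ .x$val %||% NA_character_)
      terms[[length(terms) + 1L]] <- tibble::tibble(
        term_id = node$id, label = node$lbl %||% NA_character_,
        synonyms = list(syns[!is.na(syns)]), source = src
      )
    }
    for (edge in g$edges %||% list()) {
      pred <- edge$pred %||% "is_a"
      if (pred %in% c("is_a", "subClassOf", "rdfs:subClassOf")) {
        edges[[length(edges) + 1L]] <-
          tibble::tibble(child = edge$sub, parent = edge$obj)
      }
    }
  }
  list(
    terms = if (length(terms)) dplyr::bind_rows(terms) else
      tibble::tibble(term_id = character(), label = character(),
                     synonyms = list(), source = character()),
    edges = if (length(edges)) dplyr::bind_rows(edges) else
      tibble::tibble(child = character(), parent = character())
  )
}

#' Load one or more ontologies
#'
#' Reads OBO Graphs JSON (`.json`) and/or a flat TSV dialect (columns
#' `term_id`, `label`, optional pipe-separated `synonyms` and `parents`,
#' optional `source`) and merges them into one graph. Term IDs must be
#' unique across files; only is-a edges are kept.
#'
#' @param paths Character vector of file paths.
#' @return An [ontology()] object.
#' @export
read_ontology <- function(paths) {
  parts <- purrr::map(paths, function(p) {
    if (grepl("\\.json$", p, ignore.case = TRUE)) {
      .read_ontology_obograph(p)
    } else {
      .read_ontology_tsv(p)
    }
  })
  ontology(dplyr::bind_rows(purrr::map(parts, "terms")),
           dplyr::bind_rows(purrr::map(parts, "edges")))
}

#' Write an ontology in the flat TSV dialect
#'
#' @param onto An [ontology()] object.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_ontology_tsv <- function(onto, path) {
  parents <- split(onto$edges$parent, onto$edges$child)
  out <- tibble::tibble(
    term_id = onto$terms$term_id,
    label = onto$terms$label,
    synonyms = purrr::map_chr(onto$terms$synonyms, paste, collapse = "|"),
    parents = purrr::map_chr(onto$terms$term_id,
                             ~ paste(parents[[.x]] %||% character(),
                                     collapse = "|")),
    source = onto$terms$source
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Prune an ontology to curated branches
#'
#' Retains, for each source ontology with listed keep-roots, the is-a
#' descendants (inclusive) of those roots; a term with parents in both a
#' kept and a removed branch is retained (any-ancestor rule). Sources with
#' no listed roots are kept whole. Pruning is the first step of the
#' annotation pipeline, before any matching.
#'
#' @param onto An [ontology()] object.
#' @param keep_roots Named list: source-ontology name -> character vector
#'   of root term IDs.
#' @return The pruned [ontology()].
#' @export
prune_branches <- function(onto, keep_roots) {
  stopifnot(inherits(onto, "ontology"))
  unknown <- setdiff(unlist(keep_roots), onto$terms$term_id)
  if (length(unknown) > 0L) {
    rlang::abort(sprintf("unknown keep-root term ID(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  children_of <- split(onto$edges$child, onto$edges$parent)
  descendants <- function(roots) {
    seen <- character(); queue <- roots
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (v %in% seen) next
      seen <- c(seen, v)
      queue <- c(queue, children_of[[v]] %||% character())
    }
    seen
  }
  keep <- unlist(purrr::imap(split(onto$terms$term_id, onto$terms$source),
                             function(ids, src) {
    roots <- keep_roots[[src]]
    if (is.null(roots)) ids else intersect(ids, descendants(roots))
  }))
  terms <- onto$terms[onto$terms$term_id %in% keep, ]
  edges <- onto$edges[onto$edges$child %in% keep &
                        onto$edges$parent %in% keep, ]
  ontology(terms, edges)
}

#' Build a stemmed match lexicon from an ontology
#'
#' Every primary label and synonym becomes a lexicon entry under its
#' stemmed, lowercased, punctuation-stripped form; one stem may map to
#' several term IDs (synonymy and cross-ontology duplication). Terms with
#' empty labels are skipped with a warning.
#'
#' @param onto An [ontology()] object.
#' @return Tibble with `entry_stem`, `n_tokens`, `term_ids` (list-column).
#' @export
build_lexicon <- function(onto) {
  stopifnot(inherits(onto, "ontology"), nrow(onto$terms) > 0L)
  empty <- is.na(onto$terms$label) | !nzchar(onto$terms$label)
  if (any(empty)) {
    rlang::warn(sprintf("%d term(s) with empty labels skipped: %s",
                        sum(empty),
                        paste(utils::head(onto$terms$term_id[empty], 5L),
                              collapse = ", ")))
  }
  entries <- purrr::map_dfr(which(!empty), function(i) {
    tibble::tibble(
      entry = c(onto$terms$label[[i]], onto$terms$synonyms[[i]]),
      term_id = onto$terms$term_id[[i]]
    )
  })
  if (nrow(entries) == 0L) {
    return(tibble::tibble(entry_stem = character(), n_tokens = integer(),
                          term_ids = list()))
  }
  entries$entry_stem <- stem_phrase(clean_text(entries$entry))
  entries <- entries[nzchar(entries$entry_stem), ]
  out <- dplyr::summarise(
    dplyr::group_by(entries, .data$entry_stem),
    term_ids = list(unique(.data$term_id)), .groups = "drop"
  )
  out$n_tokens <- lengths(strsplit(out$entry_stem, " ", fixed = TRUE))
  out[c("entry_stem", "n_tokens", "term_ids")]
}

# greedy leftmost-longest matching over one document's stem sequence
.annotate_one <- function(doc_id, clean_text, tokens, stems, lex_env,
                          max_len) {
  n <- length(stems)
  rows <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq.int(min(max_len, n - i + 1L), 1L)) {
      key <- paste(stems[i:(i + len - 1L)], collapse = " ")
      term_ids <- lex_env[[key]]
      if (!is.null(term_ids)) {
        start <- tokens$start[[i]]
        end <- tokens$end[[i + len - 1L]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          doc_id = doc_id,
          entry_stem = key,
          surface = substr(clean_text, start + 1L, end),
          start = start, end = end,
          first_token = i, last_token = i + len - 1L,
          term_ids = list(term_ids)
        )
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(rows) == 0L) .empty_matches() else dplyr::bind_rows(rows)
}

.empty_matches <- function() {
  tibble::tibble(doc_id = character(), entry_stem = character(),
                 surface = character(), start = integer(), end = integer(),
                 first_token = integer(), last_token = integer(),
                 term_ids = list())
}

#' Annotate a corpus against an ontology lexicon
#'
#' Greedy longest-match, left to right, over each document's stem
#' sequence: at each position the longest lexicon entry (up to `max_len`
#' tokens) wins and matching resumes after it, so nested submatches are
#' suppressed and matches never overlap. Each match records its verbatim
#' surface span in `clean_text` and all candidate term IDs.
#'
#' @param corpus Prepared corpus (needs `clean_text`, `tokens`, `stems`).
#' @param lexicon Tibble from [build_lexicon()].
#' @param max_len Longest entry considered, in tokens. Default 4: derived
#'   labels beyond 4-grams do not occur in practice.
#' @return Match tibble: `doc_id`, `entry_stem`, `surface`, `start`,
#'   `end` (0-based half-open character span), `first_token`,
#'   `last_token` (1-based token indices), `term_ids` (list-column).
#' @export
annotate_corpus <- function(corpus, lexicon, max_len = 4L) {
  lex <- lexicon[lexicon$n_tokens <= max_len, ]
  lex_env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(lex))) {
    assign(lex$entry_stem[[i]], lex$term_ids[[i]], envir = lex_env)
  }
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    .annotate_one(corpus$doc_id[[i]], corpus$clean_text[[i]],
                  corpus$tokens[[i]], corpus$stems[[i]], lex_env, max_len)
  }) -> out
  if (nrow(out) == 0L) .empty_matches() else out
}

#' Drop short single-word matches
#'
#' Single-token matches whose surface is shorter than three characters are
#' removed, except all-caps acronyms (uppercase letters/digits, length at
#' least two): "of" and "Go" go, "DNA" and "GO" stay. Multiword matches
#' are unaffected. Applied after matching.
#'
#' @param matches Match tibble from [annotate_corpus()].
#' @return The filtered match tibble.
#' @export
filter_short <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  single <- !grepl(" ", matches$surface, fixed = TRUE)
  short <- nchar(matches$surface) < 3L
  acronym <- grepl("^[A-Z0-9]+$", matches$surface) &
    nchar(matches$surface) >= 2L
  matches[!(single & short & !acronym), ]
}

#' Part-of-speech and blocklist filter for matches
#'
#' Optional context filter: with a tagger configured, a match is kept only
#' if the tag of its head token (the final token of the span) is in
#' `keep_tags`; without one the tagging stage is the identity. A stemmed
#' blocklist (e.g. geographic names, corpus-specific stop concepts)
#' removes matches regardless of tagging. A tagger error skips the tagging
#' stage with a warning rather than failing the pipeline.
#'
#' @param matches Match tibble.
#' @param corpus Prepared corpus the matches came from.
#' @param keep_tags Tags to keep; default noun-like.
#' @param tagger `NULL`, or a function taking a character vector of tokens
#'   and returning a same-length character vector of tags.
#' @param blocklist Character vector of phrases to remove (compared on
#'   stems).
#' @return The filtered match tibble.
#' @export
pos_filter <- function(matches, corpus, keep_tags = c("NOUN", "PROPN"),
                       tagger = NULL, blocklist = character()) {
  if (nrow(matches) == 0L) return(matches)
  if (length(blocklist) > 0L) {
    matches <- matches[!matches$entry_stem %in% stem_phrase(blocklist), ]
  }
  if (is.null(tagger) || nrow(matches) == 0L) return(matches)
  tags_by_doc <- tryCatch(
    stats::setNames(
      purrr::map(seq_len(nrow(corpus)), function(i) {
        tags <- tagger(corpus$tokens[[i]]$token)
        stopifnot(length(tags) == nrow(corpus$tokens[[i]]))
        tags
      }),
      corpus$doc_id
    ),
    error = function(e) {
      rlang::warn(paste("POS tagger failed; tagging stage skipped:",
                        conditionMessage(e)))
      NULL
    }
  )
  if (is.null(tags_by_doc)) return(matches)
  head_tag <- purrr::map2_chr(matches$doc_id, matches$last_token,
                              ~ tags_by_doc[[.x]][[.y]])
  matches[head_tag %in% keep_tags, ]
}

#' Build a document-frequency index over matches
#'
#' Counts, for each matched entry stem, the number of distinct documents
#' containing at least one match of it; DF(stem) = doc_count / N.
#'
#' @param matches Match tibble (any number of documents).
#' @param n_docs Corpus size N (the denominator); must cover every doc in
#'   `matches`.
#' @return A `df_index` tibble: `entry_stem`, `doc_count`, `df`, with the
#'   corpus size in the `"corpus_size"` attribute.
#' @export
build_df_index <- function(matches, n_docs) {
  stopifnot(n_docs >= 1L,
            dplyr::n_distinct(matches$doc_id) <= n_docs)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(matches[c("doc_id", "entry_stem")]),
                    .data$entry_stem),
    doc_count = dplyr::n_distinct(.data$doc_id), .groups = "drop"
  )
  out$df <- out$doc_count / n_docs
  out <- dplyr::arrange(out, .data$entry_stem)
  attr(out, "corpus_size") <- as.integer(n_docs)
  class(out) <- c("df_index", class(out))
  out
}

#' Keep rare matches as ontology labels
#'
#' A stem passes a threshold t iff its document count is at most
#' `max(1, ceiling(t * N))`: at t = 1% over 184 documents that keeps
#' stems in at most two documents, and t = 100% keeps everything. Kept
#' stems become ontology-source labels scored by DF and ranked rarest
#' first (ties alphabetical).
#'
#' @param matches Match tibble for the documents to label.
#' @param df_index A [build_df_index()] result.
#' @param threshold DF threshold t, a fraction in (0, 1].
#' @return Label tibble: `doc_id`, `phrase` (first surface form seen in
#'   the document), `stem`, `source = "ontology"`, `score` (DF).
#' @export
apply_df_threshold <- function(matches, df_index, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- attr(df_index, "corpus_size")
  max_count <- max(1L, as.integer(ceiling(threshold * n)))
  kept_stems <- df_index$entry_stem[df_index$doc_count <= max_count]
  m <- matches[matches$entry_stem %in% kept_stems, ]
  if (nrow(m) == 0L) {
    return(tibble::tibble(doc_id = character(), phrase = character(),
                          stem = character(), source = character(),
                          score = double()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(m[c("doc_id", "entry_stem",
                                          "surface")]),
                    .data$doc_id, .data$entry_stem),
    phrase = dplyr::first(.data$surface), .groups = "drop"
  )
  out$score <- df_index$df[match(out$entry_stem, df_index$entry_stem)]
  out <- dplyr::arrange(out, .data$doc_id, .data$score, .data$entry_stem)
  tibble::tibble(doc_id = out$doc_id, phrase = out$phrase,
                 stem = out$entry_stem, source = "ontology",
                 score = out$score)
}

#' Derive ontology labels for a whole corpus
#'
#' Composes the annotation pipeline: branch pruning, lexicon building,
#' greedy matching, the short-word filter, the optional POS/blocklist
#' filter, document-frequency indexing, and threshold filtering.
#'
#' @inheritParams prune_branches
#' @inheritParams annotate_corpus
#' @inheritParams pos_filter
#' @inheritParams apply_df_threshold
#' @param keep_roots `NULL` (keep every branch) or a named list as in
#'   [prune_branches()].
#' @return Label tibble as in [apply_df_threshold()], with the match table
#'   in the `"matches"` attribute and the DF index in `"df_index"`.
#' @export
derive_ontology_labels <- function(corpus, onto, keep_roots = NULL,
                                   threshold = 0.01, max_len = 4L,
                                   keep_tags = c("NOUN", "PROPN"),
                                   tagger = NULL, blocklist = character()) {
  if (!is.null(keep_roots)) onto <- prune_branches(onto, keep_roots)
  lexicon <- build_lexicon(onto)
  matches <- annotate_corpus(corpus, lexicon, max_len = max_len)
  matches <- filter_short(matches)
  matches <- pos_filter(matches, corpus, keep_tags = keep_tags,
                        tagger = tagger, blocklist = blocklist)
  df_index <- build_df_index(matches, n_docs = nrow(corpus))
  labels <- apply_df_threshold(matches, df_index, threshold)
  attr(labels, "matches") <- matches
  attr(labels, "df_index") <- df_index
  labels
}

#' Write a match table as TSV
#'
#' @param matches Match tibble.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(matches, path) {
  out <- matches
  out$term_ids <- purrr::map_chr(out$term_ids, paste, collapse = "|")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
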