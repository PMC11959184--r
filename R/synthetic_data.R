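# Seeded synthetic corpora with planted ground truth. Documents are
# pseudo-word filler with known label phrases embedded verbatim; keyword
# records carry those planted phrases plus distractors that are verifiably
# absent from the text; the toy ontology holds the planted domain terms in
# curated branches plus decoy branches built from filler vocabulary (so an
# unpruned search would match them). Everything is reproducible from the
# spec seed.

#' Specification for a synthetic corpus
#'
#' Defaults emulate the shape of a real proposal corpus: a minority of
#' documents carry publication links, labels are mostly unigrams
#' (85/14/1 percent uni/bi/trigrams, the composition observed for
#' author-assigned keywords), and each linked record carries a few
#' keywords that do not occur in the proposal text.
#'
#' @param n_docs Number of documents.
#' @param doc_length Range (min, max) of filler tokens per document.
#' @param domain_vocab_size Distinct domain pseudo-words (label material).
#' @param generic_vocab_size Distinct filler pseudo-words.
#' @param planted_labels_per_doc Range of planted labels per document.
#' @param multiword_fraction Fraction of planted labels with 2-3 tokens.
#' @param trigram_fraction_of_multi Fraction of the multiword labels that
#'   are trigrams rather than bigrams.
#' @param linked_fraction Fraction of documents given keyword records.
#' @param distractors_per_record Record keywords deliberately absent from
#'   the linked document.
#' @param n_unlinked_records Extra records with no document links.
#' @param ontology_sources,branches_per_source,terms_per_branch Toy
#'   ontology shape (>= 2 sources x >= 2 branches so pruning is
#'   exercisable).
#' @param synonym_fraction Fraction of kept-branch terms given a synonym.
#' @param seed Integer seed; identical spec + seed reproduce identical
#'   outputs.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_docs = 50L, doc_length = c(80L, 160L),
                           domain_vocab_size = 150L,
                           generic_vocab_size = 400L,
                           planted_labels_per_doc = c(3L, 8L),
                           multiword_fraction = 0.155,
                           trigram_fraction_of_multi = 0.085,
                           linked_fraction = 0.4,
                           distractors_per_record = 3L,
                           n_unlinked_records = 2L,
                           ontology_sources = 2L,
                           branches_per_source = 2L,
                           terms_per_branch = 25L,
                           synonym_fraction = 0.2, seed = 1L) {
  stopifnot(n_docs >= 1L, all(doc_length >= 1L),
            doc_length[1] <= doc_length[2],
            domain_vocab_size >= 1L, generic_vocab_size >= 1L,
            all(planted_labels_per_doc >= 1L),
            multiword_fraction >= 0, multiword_fraction <= 1,
            trigram_fraction_of_multi >= 0,
            trigram_fraction_of_multi <= 1,
            linked_fraction >= 0, linked_fraction <= 1,
            distractors_per_record >= 0L, ontology_sources >= 2L,
            branches_per_source >= 2L, terms_per_branch >= 1L,
            synonym_fraction >= 0, synonym_fraction <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# deterministic pseudo-word maker: pronounceable, stem-distinct words
.make_vocab <- function(n, forbidden_stems = character()) {
  onsets <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
              "v", "z", "br", "dr", "gr", "kr", "pl", "sk", "st", "tr")
  vowels <- c("a", "e", "i", "o", "u")
  codas <- c("", "", "l", "n", "r", "x", "m")
  words <- character(); stems <- forbidden_stems
  guard <- 0L
  while (length(words) < n) {
    guard <- guard + 1L
    if (guard > n * 200L) {
      rlang::abort("vocabulary too small to satisfy distinctness constraints")
    }
    k <- sample(2:3, 1L)
    w <- paste0(paste0(sample(onsets, k, replace = TRUE),
                       sample(vowels, k, replace = TRUE), collapse = ""),
                sample(codas, 1L))
    if (nchar(w) < 4L || w %in% stopwords_en()) next
    s <- porter_stem(w)
    if (s %in% stems) next
    words <- c(words, w); stems <- c(stems, s)
  }
  words
}

.sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

# pluralize sometimes, so record keywords exercise stemmed matching
.vary_surface <- function(phrase) {
  if (stats::runif(1) < 0.3) {
    words <- strsplit(phrase, " ", fixed = TRUE)[[1]]
    last <- words[[length(words)]]
    varied <- paste0(last, "s")
    if (porter_stem(varied) == porter_stem(last)) {
      words[[length(words)]] <- varied
      return(paste(words, collapse = " "))
    }
  }
  phrase
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Builds documents (the eight semantic fields, with planted label phrases
#' embedded verbatim in the title/description/summary fields), keyword
#' records for a linked subset (planted phrases, sometimes in inflected
#' surface form, plus per-record distractor keywords built from domain
#' words guaranteed absent from that document), a toy ontology via
#' [generate_toy_ontology()], and the per-document ground-truth stems.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `corpus` (prepared corpus tibble), `records`,
#'   `ontology`, `keep_roots`, `ground_truth` (tibble `doc_id`, `stem`),
#'   `phrase_pool`, and the `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  domain <- .make_vocab(spec$domain_vocab_size)
  generic <- .make_vocab(spec$generic_vocab_size,
                         forbidden_stems = porter_stem(domain))

  # candidate label phrases over the domain vocabulary
  n_phrases <- max(spec$domain_vocab_size,
                   spec$planted_labels_per_doc[2] * 4L)
  n_multi <- round(n_phrases * spec$multiword_fraction)
  n_tri <- round(n_multi * spec$trigram_fraction_of_multi)
  unigrams <- domain
  multis <- character()
  guard <- 0L
  while (length(multis) < n_multi) {
    guard <- guard + 1L
    if (guard > n_multi * 100L) {
      rlang::abort("vocabulary too small to satisfy distinctness constraints")
    }
    k <- if (length(multis) < n_tri) 3L else 2L
    cand <- paste(sample(domain, k), collapse = " ")
    if (!cand %in% multis) multis <- c(multis, cand)
  }
  phrase_pool <- c(unigrams, multis)

  doc_ids <- sprintf("DOC%03d", seq_len(spec$n_docs))
  planted <- vector("list", spec$n_docs)
  fields <- default_semantic_fields()
  docs <- purrr::map_dfr(seq_len(spec$n_docs), function(i) {
    n_planted <- .sample_range(spec$planted_labels_per_doc)
    n_multi_doc <- stats::rbinom(1L, n_planted, spec$multiword_fraction)
    phrases <- c(
      sample(multis, min(n_multi_doc, length(multis))),
      sample(unigrams, n_planted - min(n_multi_doc, length(multis)))
    )
    planted[[i]] <<- phrases
    n_filler <- .sample_range(spec$doc_length)
    filler <- sample(generic, n_filler, replace = TRUE)
    # title holds the first phrase; the rest go into description/summary
    title <- paste(c(phrases[[1]], sample(generic, 3L)), collapse = " ")
    rest <- phrases[-1]
    half <- length(rest) %/% 2L
    weave <- function(phr, fill) {
      if (length(phr) == 0L) return(paste(fill, collapse = " "))
      cuts <- sort(sample(0:length(fill), length(phr)))
      parts <- character()
      prev <- 0L
      for (j in seq_along(phr)) {
        parts <- c(parts, fill[seq_len(cuts[j] - prev) + prev], phr[[j]])
        prev <- cuts[j]
      }
      paste(c(parts, fill[seq_len(length(fill) - prev) + prev]),
            collapse = " ")
    }
    description <- weave(utils::head(rest, half),
                         utils::head(filler, n_filler %/% 2L))
    summary_of_work <- weave(utils::tail(rest, length(rest) - half),
                             utils::tail(filler, n_filler - n_filler %/% 2L))
    row <- stats::setNames(as.list(rep("", length(fields))), fields)
    row$title <- title
    row$description <- description
    row$`summary of work` <- summary_of_work
    row$justification <- paste(sample(generic, 6L), collapse = " ")
    row$`DOE mission` <- paste(sample(generic, 4L), collapse = " ")
    dplyr::bind_cols(tibble::tibble(doc_id = doc_ids[[i]]),
                     tibble::as_tibble(row))
  })
  docs$text <- apply(docs[fields], 1L, function(row) {
    paste(row[nzchar(row)], collapse = " ")
  })
  corpus <- prepare_corpus(docs)

  ground_truth <- purrr::map_dfr(seq_len(spec$n_docs), function(i) {
    tibble::tibble(doc_id = doc_ids[[i]],
                   stem = stem_phrase(planted[[i]]))
  })

  # keyword records for the linked subset
  n_linked <- round(spec$n_docs * spec$linked_fraction)
  linked_idx <- sort(sample(spec$n_docs, n_linked))
  rec_counter <- 0L
  records <- purrr::map_dfr(linked_idx, function(i) {
    phrases <- planted[[i]]
    doc_words <- unique(unlist(strsplit(phrases, " ", fixed = TRUE)))
    n_rec <- if (stats::runif(1) < 0.3 && length(phrases) >= 2L) 2L else 1L
    split_id <- if (n_rec == 2L) {
      sample(rep(1:2, length.out = length(phrases)))
    } else {
      rep(1L, length(phrases))
    }
    purrr::map_dfr(seq_len(n_rec), function(r) {
      rec_counter <<- rec_counter + 1L
      mine <- phrases[split_id == r]
      distract_pool <- setdiff(domain, doc_words)
      distractors <- sample(distract_pool,
                            min(spec$distractors_per_record,
                                length(distract_pool)))
      kws <- c(vapply(mine, .vary_surface, character(1),
                      USE.NAMES = FALSE), distractors)
      src <- sample(keyword_sources(), length(kws), replace = TRUE)
      tibble::tibble(
        record_id = sprintf("PUB%03d", rec_counter),
        linked_doc_ids = list(doc_ids[[i]]),
        keywords = list(stats::setNames(
          lapply(keyword_sources(), function(s) unname(kws[src == s])),
          keyword_sources()))
      )
    })
  })
  if (spec$n_unlinked_records > 0L) {
    unlinked <- purrr::map_dfr(seq_len(spec$n_unlinked_records), function(j) {
      tibble::tibble(
        record_id = sprintf("PUBX%02d", j),
        linked_doc_ids = list(character()),
        keywords = list(stats::setNames(
          list(sample(domain, 2L), character(), character()),
          keyword_sources()))
      )
    })
    records <- dplyr::bind_rows(records, unlinked)
  }

  onto <- generate_toy_ontology(spec, domain_phrases = sample(phrase_pool),
                                decoy_vocab = generic)

  list(corpus = corpus, records = records, ontology = onto$ontology,
       keep_roots = onto$keep_roots, ground_truth = ground_truth,
       planted = stats::setNames(planted, doc_ids),
       linked_doc_ids = doc_ids[linked_idx],
       phrase_pool = phrase_pool, spec = spec)
}

#' Generate a toy ontology with kept and decoy branches
#'
#' Builds `ontology_sources` source ontologies, each with
#' `branches_per_source` branches under distinct roots. The first branch
#' of each source ("kept") holds domain phrases; the remaining branches
#' ("decoy") hold filler-vocabulary words that do occur in the synthetic
#' documents, so branch pruning has observable effect on annotation. A
#' fraction of kept terms get a synonym mapping to the same term ID.
#'
#' @param spec A [synthetic_spec()].
#' @param domain_phrases Phrases for the kept branches (generated from the
#'   spec seed when `NULL`).
#' @param decoy_vocab Words for decoy branches (ditto).
#' @return A list: `ontology` (an [ontology()] object) and `keep_roots`
#'   (named list suitable for [prune_branches()]).
#' @export
generate_toy_ontology <- function(spec, domain_phrases = NULL,
                                  decoy_vocab = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(domain_phrases) || is.null(decoy_vocab)) {
    set.seed(spec$seed + 1L)
    domain_phrases <- domain_phrases %||% .make_vocab(spec$domain_vocab_size)
    decoy_vocab <- decoy_vocab %||%
      .make_vocab(spec$generic_vocab_size,
                  forbidden_stems = porter_stem(domain_phrases))
  }
  terms <- list(); edges <- list()
  keep_roots <- list()
  n_keep_terms <- spec$terms_per_branch
  kept_pool <- domain_phrases
  decoy_pool <- decoy_vocab
  synonym_pool <- rev(domain_phrases)
  for (s in seq_len(spec$ontology_sources)) {
    src <- sprintf("onto%d", s)
    for (b in seq_len(spec$branches_per_source)) {
      root_id <- sprintf("%s:B%d", toupper(src), b)
      terms[[length(terms) + 1L]] <- tibble::tibble(
        term_id = root_id, label = sprintf("%s branch %d root", src, b),
        synonyms = list(character()), source = src)
      if (b == 1L) keep_roots[[src]] <- root_id
      pool <- if (b == 1L) kept_pool else decoy_pool
      n_take <- min(n_keep_terms, length(pool))
      take <- pool[seq_len(n_take)]
      if (b == 1L) kept_pool <- kept_pool[-seq_len(n_take)] else
        decoy_pool <- decoy_pool[-seq_len(n_take)]
      for (t in seq_along(take)) {
        tid <- sprintf("%s:%d%03d", toupper(src), b, t)
        syns <- character()
        if (b == 1L && length(synonym_pool) > 0L &&
            (t / n_take) <= spec$synonym_fraction) {
          syns <- synonym_pool[[1L]]
          synonym_pool <- synonym_pool[-1L]
        }
        terms[[length(terms) + 1L]] <- tibble::tibble(
          term_id = tid, label = take[[t]], synonyms = list(syns),
          source = src)
        edges[[length(edges) + 1L]] <-
          tibble::tibble(child = tid, parent = root_id)
      }
    }
  }
  list(
    ontology = ontology(dplyr::bind_rows(terms), dplyr::bind_rows(edges)),
    keep_roots = keep_roots
  )
}

#' Write a synthetic data set in the pipeline's file dialects
#'
#' Emits `corpus.csv`, `records.json`, `ontology.tsv`,
#' `ground_truth.json`, and `keep_roots.json` under `dir`.
#'
#' @param sim A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_document_table(sim$corpus, file.path(dir, "corpus.csv"))
  write_keyword_records(sim$records, file.path(dir, "records.json"))
  write_ontology_tsv(sim$ontology, file.path(dir, "ontology.tsv"))
  jsonlite::write_json(
    purrr::map(split(sim$ground_truth$stem, sim$ground_truth$doc_id),
               as.list),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(sim$keep_roots, file.path(dir, "keep_roots.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
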