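# shared in-code fixtures

# corpus tibble straight from doc texts
corpus_from_texts <- function(texts) {
  prepare_corpus(tibble::tibble(
    doc_id = names(texts) %||% sprintf("D%02d", seq_along(texts)),
    text = unname(unlist(texts))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# one keyword record row
record_row <- function(record_id, links, wos = character(),
                       pubmed = character(), mesh = character()) {
  tibble::tibble(
    record_id = record_id,
    linked_doc_ids = list(links),
    keywords = list(list(wos_author = wos, pubmed_author = pubmed,
                         mesh = mesh))
  )
}

# simple chain ontology A <- B <- C (C is-a B is-a A)
chain_ontology <- function() {
  ontology(
    terms = tibble::tibble(
      term_id = c("A", "B", "C"),
      label = c("alpha term", "beta term", "gamma term"),
      synonyms = list(character(), character(), character()),
      source = "toy"
    ),
    edges = tibble::tibble(child = c("B", "C"), parent = c("A", "B"))
  )
}

# brute-force annotation oracle: enumerate every matching span, then give
# precedence to leftmost start and longest length among non-overlapping
# spans
annotate_oracle <- function(stems, lexicon_stems, max_len = 4L) {
  n <- length(stems)
  spans <- data.frame(start = integer(), end = integer())
  for (i in seq_len(n)) {
    for (len in seq_len(min(max_len, n - i + 1L))) {
      key <- paste(stems[i:(i + len - 1L)], collapse = " ")
      if (key %in% lexicon_stems) {
        spans <- rbind(spans, data.frame(start = i, end = i + len - 1L))
      }
    }
  }
  if (nrow(spans) == 0L) return(character())
  spans <- spans[order(spans$start, -spans$end), ]
  out <- character()
  ptr <- 1L
  for (k in seq_len(nrow(spans))) {
    if (spans$start[k] < ptr) next
    out <- c(out, paste(stems[spans$start[k]:spans$end[k]], collapse = " "))
    ptr <- spans$end[k] + 1L
  }
  out
}

# independent brute-force top-N scorer used as the evaluator oracle
score_oracle <- function(label_stems, phrases, n) {
  top <- phrases[seq_len(min(n, length(phrases)))]
  top_stems <- unique(stem_phrase(top))
  lab <- unique(label_stems)
  n_matched <- sum(top_stems %in% lab)
  p <- n_matched / length(top_stems)
  r <- n_matched / length(lab)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}
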