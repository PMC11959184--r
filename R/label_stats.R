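# Descriptive analyses of derived label sets: phrase-length (n-gram)
# composition, document-frequency histogram, label co-occurrence, and
# pairwise semantic-similarity summaries.

#' n-gram length summary of labels
#'
#' Counts label occurrences (not deduplicated across documents) by the
#' number of tokens in each label's stem, with percentages.
#'
#' @param labels Label tibble with a `stem` column.
#' @return Tibble with `n`, `count`, `percent`.
#' @export
ngram_summary <- function(labels) {
  if (nrow(labels) == 0L) {
    return(tibble::tibble(n = integer(), count = integer(),
                          percent = double()))
  }
  n_tokens <- lengths(strsplit(labels$stem, " ", fixed = TRUE))
  out <- dplyr::count(tibble::tibble(n = n_tokens), .data$n,
                      name = "count")
  out$percent <- 100 * out$count / sum(out$count)
  out
}

#' Document-frequency histogram of distinct label stems
#'
#' For every distinct stem, counts the documents containing it, then
#' buckets those counts into 1, 2, 3, 4, 5, 6-10, 11-20 and >20.
#'
#' @param labels Label tibble (`doc_id`, `stem`).
#' @return Tibble with `bucket` (ordered factor), `count`, `percent`;
#'   counts sum to the number of distinct stems.
#' @export
frequency_summary <- function(labels) {
  bucket_levels <- c("1", "2", "3", "4", "5", "6-10", "11-20", ">20")
  if (nrow(labels) == 0L) {
    return(tibble::tibble(
      bucket = factor(character(), levels = bucket_levels),
      count = integer(), percent = double()))
  }
  per_stem <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(labels[c("doc_id", "stem")]),
                    .data$stem),
    doc_count = dplyr::n_distinct(.data$doc_id), .groups = "drop"
  )
  bucket <- cut(per_stem$doc_count,
                breaks = c(0, 1, 2, 3, 4, 5, 10, 20, Inf),
                labels = bucket_levels)
  out <- dplyr::count(tibble::tibble(bucket = bucket), .data$bucket,
                      name = "count", .drop = FALSE)
  out$percent <- 100 * out$count / sum(out$count)
  out
}

#' Label co-occurrence counts
#'
#' Counts, for every unordered pair of distinct label stems, the number of
#' documents whose label sets contain both (each document contributes at
#' most once per pair).
#'
#' @param labels Label tibble (`doc_id`, `stem`).
#' @return Tibble with `stem_a`, `stem_b` (`stem_a < stem_b`), `count`,
#'   sorted by decreasing count.
#' @export
cooccurrence_counts <- function(labels) {
  empty <- tibble::tibble(stem_a = character(), stem_b = character(),
                          count = integer())
  if (nrow(labels) == 0L) return(empty)
  by_doc <- purrr::map(split(labels$stem, labels$doc_id),
                       ~ sort(unique(.x)))
  pairs <- purrr::map_dfr(by_doc, function(stems) {
    if (length(stems) < 2L) return(NULL)
    idx <- utils::combn(length(stems), 2L)
    tibble::tibble(stem_a = stems[idx[1L, ]], stem_b = stems[idx[2L, ]])
  })
  if (nrow(pairs) == 0L) return(empty)
  out <- dplyr::count(pairs, .data$stem_a, .data$stem_b, name = "count")
  dplyr::arrange(out, dplyr::desc(.data$count), .data$stem_a, .data$stem_b)
}

#' Deterministic hashed embedding adapter
#'
#' A synthetic stand-in for a real phrase-embedding model: each phrase is
#' hashed to a seed and mapped to a reproducible random unit vector, so
#' identical phrases embed identically and unrelated phrases are nearly
#' orthogonal in expectation. Useful for exercising
#' [pairwise_similarity()]; it carries no semantics.
#'
#' @param dim Embedding dimension.
#' @return A function `(phrases) -> matrix` with one row per phrase.
#' @export
hash_embedding <- function(dim = 64L) {
  function(phrases) {
    vecs <- t(vapply(phrases, function(p) {
      codes <- utf8ToInt(p)
      seed <- sum(codes * seq_along(codes) * 131L) %% 2147483647L
      old <- .Random.seed_exists()
      on.exit(.restore_seed(old), add = TRUE)
      set.seed(seed)
      v <- stats::rnorm(dim)
      v / sqrt(sum(v^2))
    }, numeric(dim)))
    rownames(vecs) <- phrases
    vecs
  }
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Pairwise cosine-similarity statistics of within-document label pairs
#'
#' Embeds each document's labels with the supplied adapter and summarizes
#' the cosine similarity over all within-document label pairs. No
#' embedding is bundled with the package ([hash_embedding()] provides a
#' synthetic one for testing); phrases the adapter cannot embed (rows of
#' `NA`) cause their pairs to be skipped and counted.
#'
#' @param labels Label tibble (`doc_id`, `stem`).
#' @param embed Function `(phrases) -> matrix` (rows aligned to phrases).
#' @return A one-row tibble with `mean`, `sd`, `min`, `p5`, `median`,
#'   `p95`, `max`, `n_pairs`, `n_skipped`.
#' @export
pairwise_similarity <- function(labels, embed) {
  stopifnot(is.function(embed))
  phrases <- sort(unique(labels$stem))
  if (length(phrases) == 0L) {
    return(tibble::tibble(mean = NA_real_, sd = NA_real_, min = NA_real_,
                          p5 = NA_real_, median = NA_real_, p95 = NA_real_,
                          max = NA_real_, n_pairs = 0L, n_skipped = 0L))
  }
  vecs <- embed(phrases)
  stopifnot(is.matrix(vecs), nrow(vecs) == length(phrases))
  rownames(vecs) <- phrases
  norms <- sqrt(rowSums(vecs^2))
  by_doc <- purrr::map(split(labels$stem, labels$doc_id),
                       ~ sort(unique(.x)))
  sims <- c()
  n_skipped <- 0L
  for (stems in by_doc) {
    if (length(stems) < 2L) next
    idx <- utils::combn(length(stems), 2L)
    for (k in seq_len(ncol(idx))) {
      a <- stems[idx[1L, k]]; b <- stems[idx[2L, k]]
      va <- vecs[a, ]; vb <- vecs[b, ]
      if (anyNA(va) || anyNA(vb) || norms[[a]] == 0 || norms[[b]] == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      sims <- c(sims, sum(va * vb) / (norms[[a]] * norms[[b]]))
    }
  }
  if (length(sims) == 0L) {
    return(tibble::tibble(mean = NA_real_, sd = NA_real_, min = NA_real_,
                          p5 = NA_real_, median = NA_real_, p95 = NA_real_,
                          max = NA_real_, n_pairs = 0L,
                          n_skipped = n_skipped))
  }
  q <- stats::quantile(sims, c(0.05, 0.5, 0.95), names = FALSE)
  tibble::tibble(mean = mean(sims), sd = stats::sd(sims), min = min(sims),
                 p5 = q[[1]], median = q[[2]], p95 = q[[3]],
                 max = max(sims), n_pairs = length(sims),
                 n_skipped = n_skipped)
}

#' Full descriptive report over a label table
#'
#' @param labels Label tibble.
#' @param embed Optional embedding adapter for the similarity block.
#' @return A `label_stats` list with `ngram_counts`, `freq_histogram`,
#'   `cooccurrence`, and (when `embed` is given) `similarity_stats`.
#' @export
label_stats <- function(labels, embed = NULL) {
  structure(
    list(
      ngram_counts = ngram_summary(labels),
      freq_histogram = frequency_summary(labels),
      cooccurrence = cooccurrence_counts(labels),
      similarity_stats = if (is.null(embed)) NULL else
        pairwise_similarity(labels, embed)
    ),
    class = "label_stats"
  )
}

#' @export
print.label_stats <- function(x, ...) {
  cat("label length (tokens):\n"); print(x$ngram_counts)
  cat("\ndocument-frequency histogram:\n"); print(x$freq_histogram)
  cat(sprintf("\nco-occurring pairs: %d (top shown)\n",
              nrow(x$cooccurrence)))
  print(utils::head(x$cooccurrence, 5L))
  if (!is.null(x$similarity_stats)) {
    cat("\npairwise cosine similarity:\n"); print(x$similarity_stats)
  }
  invisible(x)
}

#' Plot the n-gram composition of a label set
#'
#' @param labels Label tibble.
#' @return A ggplot bar chart.
#' @export
plot_ngram_summary <- function(labels) {
  ggplot2::ggplot(ngram_summary(labels),
                  ggplot2::aes(x = factor(.data$n), y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "label length (tokens)", y = "% of labels") +
    ggplot2::theme_minimal()
}
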