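# Validation of machine keyphrases against derived labels: stemmed exact
# matching, precision/recall/F-1 at top-N, and the exhaustive
# hyperparameter grid search.

#' Match machine keyphrases against derived labels
#'
#' Both sides are normalized with [stem_phrase()]; a machine phrase counts
#' as correct only when its full stemmed phrase equals some label stem
#' (no partial credit: "evolut" does not match the label
#' "evolut of symbiosi"). Duplicates collapse.
#'
#' @param ml_phrases Ranked machine keyphrases (character).
#' @param labels Label tibble with a `stem` column, or a character vector
#'   of label phrases.
#' @return Character vector: the matched stems (a subset of the label
#'   stems).
#' @export
match_keywords <- function(ml_phrases, labels) {
  label_stems <- if (is.character(labels)) stem_phrase(labels) else
    labels$stem
  intersect(unique(stem_phrase(ml_phrases)), unique(label_stems))
}

#' F-1 from precision and recall
#'
#' Harmonic mean of precision and recall, with the 0/0 -> 0 convention
#' (the harmonic mean is undefined when both are zero).
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return Numeric vector of F-1 scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision, recall and F-1 from match counts
#'
#' @param n_matched Number of correctly matched keywords.
#' @param n_extracted Total extracted keywords (>= 1).
#' @param n_labels Total derived labels (>= 1); documents with zero labels
#'   must be excluded upstream, never divided by.
#' @return A one-row tibble with `precision`, `recall`, `f1`.
#' @export
prf <- function(n_matched, n_extracted, n_labels) {
  stopifnot(n_extracted >= 1L, n_labels >= 1L,
            n_matched >= 0L, n_matched <= min(n_extracted, n_labels))
  precision <- n_matched / n_extracted
  recall <- n_matched / n_labels
  tibble::tibble(precision = precision, recall = recall,
                 f1 = f1_score(precision, recall))
}

#' Evaluate extracted keyphrases against derived labels
#'
#' For each document with at least one label and one keyword, the first N
#' keyphrases are stemmed, deduplicated, and exact-matched against the
#' document's label stems; per-document precision/recall/F-1 are then
#' macro-averaged (arithmetic mean over scored documents; a pooled
#' micro-average is available behind `average = "micro"`). Documents
#' lacking labels or keywords are skipped and listed with reasons.
#'
#' @param labels Label tibble (`doc_id`, `stem`).
#' @param keywords Keyword tibble (`doc_id`, `rank`, `phrase`).
#' @param n_values Top-N cutoffs, by default 5/10/20.
#' @param average `"macro"` (default) or `"micro"`.
#' @return A `keyphrase_eval` object: `per_doc` and `aggregate` tibbles,
#'   the skip list, `n_values`, `n_docs_scored`. [tidy()] returns the
#'   per-document table, [glance()] the aggregate in one row.
#' @export
evaluate_corpus <- function(labels, keywords, n_values = c(5L, 10L, 20L),
                            average = c("macro", "micro")) {
  average <- match.arg(average)
  stopifnot(all(n_values >= 1L))
  label_docs <- unique(labels$doc_id)
  kw_docs <- unique(keywords$doc_id)
  scored_docs <- intersect(label_docs, kw_docs)
  if (length(scored_docs) == 0L) {
    rlang::abort("no document has both derived labels and keywords")
  }
  skipped <- dplyr::bind_rows(
    tibble::tibble(doc_id = setdiff(label_docs, kw_docs),
                   reason = "no extracted keywords"),
    tibble::tibble(doc_id = setdiff(kw_docs, label_docs),
                   reason = "no derived labels")
  )
  label_stems <- purrr::map(
    split(labels$stem, labels$doc_id), unique)
  kw_sorted <- keywords[order(keywords$doc_id, keywords$rank), ]
  kw_by_doc <- split(kw_sorted$phrase, kw_sorted$doc_id)

  per_doc <- purrr::map_dfr(scored_docs, function(d) {
    lab <- label_stems[[d]]
    phrases <- kw_by_doc[[d]]
    purrr::map_dfr(sort(unique(as.integer(n_values))), function(n) {
      top <- unique(stem_phrase(utils::head(phrases, n)))
      matched <- intersect(top, lab)
      cbind(
        tibble::tibble(doc_id = d, n = n, n_matched = length(matched),
                       n_extracted = length(top), n_labels = length(lab)),
        prf(length(matched), length(top), length(lab))
      )
    })
  })
  per_doc <- tibble::as_tibble(per_doc)

  aggregate <- if (average == "macro") {
    dplyr::summarise(
      dplyr::group_by(per_doc, .data$n),
      precision = mean(.data$precision), recall = mean(.data$recall),
      f1 = mean(.data$f1), .groups = "drop"
    )
  } else {
    agg <- dplyr::summarise(
      dplyr::group_by(per_doc, .data$n),
      precision = sum(.data$n_matched) / sum(.data$n_extracted),
      recall = sum(.data$n_matched) / sum(.data$n_labels),
      .groups = "drop"
    )
    agg$f1 <- f1_score(agg$precision, agg$recall)
    agg
  }

  structure(
    list(per_doc = per_doc, aggregate = aggregate,
         n_values = sort(unique(as.integer(n_values))),
         n_docs_scored = length(scored_docs), skipped = skipped,
         average = average),
    class = "keyphrase_eval"
  )
}

#' @export
print.keyphrase_eval <- function(x, ...) {
  cat(sprintf("<keyphrase_eval: %d document(s) scored, %s-averaged>\n",
              x$n_docs_scored, x$average))
  print(x$aggregate)
  if (nrow(x$skipped) > 0L) {
    cat(sprintf("%d document(s) skipped\n", nrow(x$skipped)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname evaluate_corpus
#' @param x A `keyphrase_eval` object.
#' @param ... Unused.
#' @export
tidy.keyphrase_eval <- function(x, ...) {
  x$per_doc
}

#' @rdname evaluate_corpus
#' @export
glance.keyphrase_eval <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$aggregate, names_from = "n",
    values_from = c("precision", "recall", "f1"), names_sep = "_at_")
  wide$n_docs_scored <- x$n_docs_scored
  wide$n_docs_skipped <- nrow(x$skipped)
  wide
}

#' Plot corpus-level scores by top-N cutoff
#'
#' @param object A `keyphrase_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.keyphrase_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$aggregate, c("precision", "recall",
                                                  "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$n_values) +
    ggplot2::labs(x = "top-N cutoff", y = "score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Exhaustive hyperparameter grid search
#'
#' Enumerates the full Cartesian product of the axes (the default grid has
#' 135 combinations), extracts keywords for every combination, scores them
#' against the labels, and reports the argmax of aggregate F-1 for each
#' top-N cutoff. Ties are broken by the deterministic lexicographic order
#' on (ngram, window, dedup_method, dedup_threshold); all tied winners are
#' listed.
#'
#' @param corpus Prepared corpus.
#' @param labels Label tibble.
#' @param extractor Adapter name.
#' @param axes Named list of axis values; see [default_grid_axes()].
#' @param n_values Top-N cutoffs.
#' @return A `keyphrase_grid` object with `table` (one row per combination
#'   per N) and `best` (per-N winner plus the tied set). [tidy()] returns
#'   the table, [glance()] the winners.
#' @export
grid_search <- function(corpus, labels, extractor = "frequency",
                        axes = default_grid_axes(),
                        n_values = c(5L, 10L, 20L)) {
  stopifnot(all(lengths(axes) > 0L),
            all(c("ngram", "window", "dedup_method", "dedup_threshold")
                %in% names(axes)))
  combos <- tidyr::expand_grid(
    ngram = sort(unique(as.integer(axes$ngram))),
    window = sort(unique(as.integer(axes$window))),
    dedup_method = sort(unique(as.character(axes$dedup_method))),
    dedup_threshold = sort(unique(as.numeric(axes$dedup_threshold)))
  )
  combos$combo_id <- seq_len(nrow(combos))
  flagged <- integer()
  table <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    params <- extractor_params(
      ngram = combos$ngram[[i]], window = combos$window[[i]],
      dedup_method = combos$dedup_method[[i]],
      dedup_threshold = combos$dedup_threshold[[i]],
      top_n = max(n_values)
    )
    keywords <- suppressWarnings(batch_extract(corpus, params, extractor))
    if (length(attr(keywords, "failures")) > 0L) {
      flagged <<- c(flagged, i)
    }
    scores <- evaluate_corpus(labels, keywords, n_values)$aggregate
    dplyr::bind_cols(combos[rep(i, nrow(scores)), ], scores)
  })
  best <- purrr::map_dfr(sort(unique(as.integer(n_values))), function(n) {
    sub <- table[table$n == n, ]
    top <- max(sub$f1)
    tied <- sub[sub$f1 == top, ]
    winner <- tied[which.min(tied$combo_id), ]
    winner$tied <- list(tied[c("combo_id", "ngram", "window",
                               "dedup_method", "dedup_threshold", "f1")])
    winner
  })
  structure(
    list(table = tibble::as_tibble(table), best = tibble::as_tibble(best),
         n_combinations = nrow(combos), flagged = combos$combo_id[flagged]),
    class = "keyphrase_grid"
  )
}

#' @export
print.keyphrase_grid <- function(x, ...) {
  cat(sprintf("<keyphrase_grid: %d combinations>\n", x$n_combinations))
  print(x$best[c("n", "ngram", "window", "dedup_method", "dedup_threshold",
                 "f1")])
  invisible(x)
}

#' @rdname grid_search
#' @param x A `keyphrase_grid` object.
#' @param ... Unused.
#' @export
tidy.keyphrase_grid <- function(x, ...) {
  x$table
}

#' @rdname grid_search
#' @export
glance.keyphrase_grid <- function(x, ...) {
  out <- x$best
  out$n_tied <- purrr::map_int(out$tied, nrow)
  out$tied <- NULL
  out$n_combinations <- x$n_combinations
  out
}

#' Plot grid-search F-1 across combinations
#'
#' @param object A `keyphrase_grid` object.
#' @param ... Unused.
#' @return A ggplot faceted by top-N cutoff.
#' @export
autoplot.keyphrase_grid <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$combo_id, y = .data$f1)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "combination (lexicographic order)", y = "F-1") +
    ggplot2::theme_minimal()
}

#' Write evaluation results as JSON / grid results as CSV
#'
#' @param scores A `keyphrase_eval` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(scores, path) {
  jsonlite::write_json(
    list(aggregate = scores$aggregate, per_doc = scores$per_doc,
         skipped = scores$skipped, n_docs_scored = scores$n_docs_scored,
         average = scores$average),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' @param grid A `keyphrase_grid` object.
#' @rdname write_eval_json
#' @export
write_grid_csv <- function(grid, path) {
  readr::write_csv(grid$table, path, progress = FALSE)
  invisible(path)
}
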