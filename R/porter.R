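# Porter stemming algorithm (Porter 1980), in the variant popularised by
# NLTK: the original rule tables plus the small set of community
# extensions (irregular-form pool, one-syllable -ies/-ied handling,
# y -> i only after a non-initial consonant, ALLI -> AL applied early,
# FULLI/LOGI rules, and words of <= 2 letters left alone). These
# extensions change the stems of common English words ("dies", "enjoy",
# "sky"), so matching them matters when labels produced elsewhere are
# compared by stem equality.

.porter_vowels <- c("a", "e", "i", "o", "u")

# consonant/vowel flags for each character; "y" is a consonant iff it
# starts the word or follows a vowel
.porter_flags <- function(chars) {
  n <- length(chars)
  flags <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[[i]]
    if (ch %in% .porter_vowels) {
      flags[[i]] <- FALSE
    } else if (ch == "y") {
      flags[[i]] <- if (i == 1L) TRUE else !flags[[i - 1L]]
    } else {
      flags[[i]] <- TRUE
    }
  }
  flags
}

.porter_measure <- function(word) {
  if (!nzchar(word)) return(0L)
  flags <- .porter_flags(strsplit(word, "", fixed = TRUE)[[1]])
  # count v -> c transitions
  if (length(flags) < 2L) return(0L)
  sum(!flags[-length(flags)] & flags[-1L])
}

.porter_contains_vowel <- function(word) {
  if (!nzchar(word)) return(FALSE)
  any(!.porter_flags(strsplit(word, "", fixed = TRUE)[[1]]))
}

.porter_is_consonant_at <- function(word, i) {
  .porter_flags(strsplit(word, "", fixed = TRUE)[[1]])[[i]]
}

.porter_ends_double_consonant <- function(word) {
  n <- nchar(word)
  n >= 2L &&
    substr(word, n, n) == substr(word, n - 1L, n - 1L) &&
    .porter_is_consonant_at(word, n)
}

# condition *o, with the two-letter vowel-consonant extension
.porter_ends_cvc <- function(word) {
  n <- nchar(word)
  if (n >= 3L) {
    flags <- .porter_flags(strsplit(word, "", fixed = TRUE)[[1]])
    last <- substr(word, n, n)
    if (flags[[n - 2L]] && !flags[[n - 1L]] && flags[[n]] &&
        !last %in% c("w", "x", "y")) {
      return(TRUE)
    }
  }
  if (n == 2L) {
    flags <- .porter_flags(strsplit(word, "", fixed = TRUE)[[1]])
    return(!flags[[1L]] && flags[[2L]])
  }
  FALSE
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# first-match-wins rule application: if a suffix matches but its
# condition fails, stop without trying later rules (Porter's semantics)
.porter_rules <- function(word, rules) {
  for (rule in rules) {
    suffix <- rule[[1]]; replacement <- rule[[2]]; condition <- rule[[3]]
    if (identical(suffix, "*d")) {
      if (.porter_ends_double_consonant(word)) {
        stem <- .chop(word, 2L)
        if (is.null(condition) || condition(stem)) {
          return(paste0(stem, replacement))
        }
        return(word)
      }
      next
    }
    if (endsWith(word, suffix)) {
      stem <- .chop(word, nchar(suffix))
      if (is.null(condition) || condition(stem)) {
        return(paste0(stem, replacement))
      }
      return(word)
    }
  }
  word
}

.porter_pool <- c(
  sky = "sky", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  news = "news", innings = "inning", inning = "inning", outings = "outing",
  outing = "outing", cannings = "canning", canning = "canning",
  howe = "howe", proceed = "proceed", exceed = "exceed", succeed = "succeed"
)

.porter_step1a <- function(word) {
  if (endsWith(word, "ies") && nchar(word) == 4L) {
    return(paste0(.chop(word, 3L), "ie"))
  }
  .porter_rules(word, list(
    list("sses", "ss", NULL),
    list("ies", "i", NULL),
    list("ss", "ss", NULL),
    list("s", "", NULL)
  ))
}

.porter_step1b <- function(word) {
  if (endsWith(word, "ied")) {
    if (nchar(word) == 4L) return(paste0(.chop(word, 3L), "ie"))
    return(paste0(.chop(word, 3L), "i"))
  }
  if (endsWith(word, "eed")) {
    stem <- .chop(word, 3L)
    if (.porter_measure(stem) > 0L) return(paste0(stem, "ee"))
    return(word)
  }
  stem <- NULL
  for (suffix in c("ed", "ing")) {
    if (endsWith(word, suffix)) {
      candidate <- .chop(word, nchar(suffix))
      if (.porter_contains_vowel(candidate)) {
        stem <- candidate
        break
      }
    }
  }
  if (is.null(stem)) return(word)
  last <- substr(stem, nchar(stem), nchar(stem))
  .porter_rules(stem, list(
    list("at", "ate", NULL),
    list("bl", "ble", NULL),
    list("iz", "ize", NULL),
    list("*d", last, function(s) !last %in% c("l", "s", "z")),
    list("", "e", function(s) {
      .porter_measure(s) == 1L && .porter_ends_cvc(s)
    })
  ))
}

.porter_step1c <- function(word) {
  .porter_rules(word, list(
    list("y", "i", function(stem) {
      nchar(stem) > 1L && .porter_is_consonant_at(stem, nchar(stem))
    })
  ))
}

.porter_step2 <- function(word) {
  m_pos <- function(stem) .porter_measure(stem) > 0L
  if (endsWith(word, "alli") && m_pos(.chop(word, 4L))) {
    return(.porter_step2(paste0(.chop(word, 4L), "al")))
  }
  .porter_rules(word, list(
    list("ational", "ate", m_pos),
    list("tional", "tion", m_pos),
    list("enci", "ence", m_pos),
    list("anci", "ance", m_pos),
    list("izer", "ize", m_pos),
    list("bli", "ble", m_pos),
    list("alli", "al", m_pos),
    list("entli", "ent", m_pos),
    list("eli", "e", m_pos),
    list("ousli", "ous", m_pos),
    list("ization", "ize", m_pos),
    list("ation", "ate", m_pos),
    list("ator", "ate", m_pos),
    list("alism", "al", m_pos),
    list("iveness", "ive", m_pos),
    list("fulness", "ful", m_pos),
    list("ousness", "ous", m_pos),
    list("aliti", "al", m_pos),
    list("iviti", "ive", m_pos),
    list("biliti", "ble", m_pos),
    list("fulli", "ful", m_pos),
    # the "l" of -logi stays with the stem so geo-/theo- behave like
    # longer stems
    list("logi", "log", function(stem) m_pos(.chop(word, 3L)))
  ))
}

.porter_step3 <- function(word) {
  m_pos <- function(stem) .porter_measure(stem) > 0L
  .porter_rules(word, list(
    list("icate", "ic", m_pos),
    list("ative", "", m_pos),
    list("alize", "al", m_pos),
    list("iciti", "ic", m_pos),
    list("ical", "ic", m_pos),
    list("ful", "", m_pos),
    list("ness", "", m_pos)
  ))
}

.porter_step4 <- function(word) {
  m_gt1 <- function(stem) .porter_measure(stem) > 1L
  .porter_rules(word, list(
    list("al", "", m_gt1),
    list("ance", "", m_gt1),
    list("ence", "", m_gt1),
    list("er", "", m_gt1),
    list("ic", "", m_gt1),
    list("able", "", m_gt1),
    list("ible", "", m_gt1),
    list("ant", "", m_gt1),
    list("ement", "", m_gt1),
    list("ment", "", m_gt1),
    list("ent", "", m_gt1),
    list("ion", "", function(stem) {
      .porter_measure(stem) > 1L &&
        substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
    }),
    list("ou", "", m_gt1),
    list("ism", "", m_gt1),
    list("ate", "", m_gt1),
    list("iti", "", m_gt1),
    list("ous", "", m_gt1),
    list("ive", "", m_gt1),
    list("ize", "", m_gt1)
  ))
}

.porter_step5a <- function(word) {
  if (endsWith(word, "e")) {
    stem <- .chop(word, 1L)
    m <- .porter_measure(stem)
    if (m > 1L) return(stem)
    if (m == 1L && !.porter_ends_cvc(stem)) return(stem)
  }
  word
}

.porter_step5b <- function(word) {
  if (endsWith(word, "ll") && .porter_measure(.chop(word, 1L)) > 1L) {
    return(.chop(word, 1L))
  }
  word
}

.porter_stem_one <- function(word) {
  word <- tolower(word)
  if (!is.na(.porter_pool[word])) return(unname(.porter_pool[word]))
  if (nchar(word) <= 2L) return(word)
  word <- .porter_step1a(word)
  word <- .porter_step1b(word)
  word <- .porter_step1c(word)
  word <- .porter_step2(word)
  word <- .porter_step3(word)
  word <- .porter_step4(word)
  word <- .porter_step5a(word)
  .porter_step5b(word)
}

# process-wide memo; stemming is called token-by-token over whole corpora
.porter_cache <- new.env(parent = emptyenv())

#' Porter stem of each word
#'
#' Reduces inflected English word forms to a common stem, so that
#' morphological variants (genome/genomic, sequencing/sequenced) compare
#' equal. Input is lowercased first; words of two characters or fewer are
#' returned unchanged (lowercased).
#'
#' @param words Character vector of single words (no internal whitespace).
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("genome", "genomic", "sequencing"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, function(w) {
    if (is.na(w)) return(NA_character_)
    hit <- .porter_cache[[w]]
    if (!is.null(hit)) return(hit)
    out <- .porter_stem_one(w)
    assign(w, out, envir = .porter_cache)
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize a phrase to its stemmed form
#'
#' Lowercases, strips punctuation, tokenizes on whitespace and stems each
#' token with [porter_stem()], joining the stems with single spaces. This
#' is the canonical key under which labels and machine keyphrases are
#' compared ("comparative genomics" and "compar genom" normalize
#' identically).
#'
#' @param phrases Character vector of phrases (may contain spaces and
#'   punctuation).
#' @return Character vector of stemmed phrases.
#' @examples
#' stem_phrase(c("Comparative Genomics", "amanita: thiersii"))
#' @export
stem_phrase <- function(phrases) {
  stopifnot(is.character(phrases))
  vapply(phrases, function(p) {
    if (is.na(p)) return(NA_character_)
    tokens <- stringr::str_extract_all(p, "[A-Za-z0-9]+")[[1]]
    if (length(tokens) == 0L) return("")
    paste(porter_stem(tokens), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}
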