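#' E-cigarette collection keywords
#'
#' The keyword list used to collect the e-cigarette tweet stream. Tweets are
#' considered topic-relevant when they contain at least one of these terms.
#'
#' @return Character vector of lowercase keywords.
#' @export
ecig_keywords <- function() {
  c(
    "e-cig", "e-cigs", "ecig", "ecigs", "electroniccigarette",
    "vape", "vapers", "vaping", "vapes",
    "e-liquid", "ejuice", "eliquid", "e-juice",
    "vapercon", "vapeon", "vapefam", "vapenation", "juul"
  )
}

#' Commercial-promotion keywords
#'
#' Terms marking a tweet as a commercial/promotional post; such tweets are
#' removed before any quit-mention analysis. `"$"` and `"%"` are matched as
#' raw substrings, word terms as whole tokens, and multi-word terms as token
#' phrases.
#'
#' @return Character vector of promotion keywords.
#' @export
promo_keywords <- function() {
  c(
    "dealer", "deal", "customer", "promotion", "promo", "promos",
    "discount", "sale", "free shipping", "sell", "$", "%", "dollar",
    "offer", "percent off", "store", "save", "price", "wholesale"
  )
}

#' Default stopword list
#'
#' The core function words dropped before itemset mining, plus a small
#' standard extension of English function words (the core list is
#' deliberately short; the extension is a documented choice, not part of the
#' original lexicon derivation).
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  core <- c("i", "is", "are", "do", "we", "it", "in", "on", "at", "to", "the")
  extension <- c(
    "a", "an", "and", "of", "for", "with", "my", "me", "you", "your",
    "this", "that", "was", "were", "be", "been", "am", "so", "but", "or",
    "as", "if", "its", "im", "just", "not", "no", "have", "has", "had",
    "they", "he", "she", "his", "her", "them", "there", "what", "when",
    "how", "who", "will", "would", "can", "could", "about", "from", "by",
    "up", "out", "all", "than", "then"
  )
  unique(c(core, extension))
}

#' The three policy windows
#'
#' Calendar windows (UTC dates, inclusive on both ends) delimiting the study
#' periods: before the announcement of the FDA flavor enforcement policy,
#' between announcement (2 January 2020) and implementation (6 February
#' 2020), and after implementation. Tweets from August-December 2019 fall in
#' no window and are excluded, keeping state-level flavor-policy noise out of
#' the comparison.
#'
#' @return A tibble with columns `label`, `start`, `end`.
#' @export
default_windows <- function() {
  tibble::tibble(
    label = period_levels(),
    start = as.Date(c("2019-06-13", "2020-01-02", "2020-02-06")),
    end   = as.Date(c("2019-07-31", "2020-02-05", "2020-10-12"))
  )
}

#' Study configuration
#'
#' Bundles every tunable of the pipeline: keyword lists, stopwords, the quit
#' lexicon lemmas, mining thresholds, significance level, period windows and
#' the age-group split.
#'
#' @param ecig_keywords Topic-relevance keywords.
#' @param promo_keywords Commercial-filter keywords.
#' @param stopwords Stopwords removed before mining.
#' @param quit_lemmas Default lexicon lemmas used when mining is skipped.
#' @param min_support Absolute transaction-count support threshold for
#'   frequent itemsets (default 1000).
#' @param min_rule_probability Minimum association-rule probability
#'   (confidence) for lexicon selection, in `[0, 1]` (default 0.30).
#' @param alpha Two-sided significance level for z-tests (default 0.05).
#' @param windows Three-row window tibble as from [default_windows()].
#' @param age_split Age (years) splitting young from old adults; ages in
#'   `[18, age_split)` are "young", `>= age_split` "old" (default 35).
#' @return A list of class `study_config`.
#' @examples
#' cfg <- study_config(min_support = 2)
#' cfg$quit_lemmas
#' @export
study_config <- function(ecig_keywords = vapequit::ecig_keywords(),
                         promo_keywords = vapequit::promo_keywords(),
                         stopwords = default_stopwords(),
                         quit_lemmas = c("quit", "stop"),
                         min_support = 1000L,
                         min_rule_probability = 0.30,
                         alpha = 0.05,
                         windows = default_windows(),
                         age_split = 35L) {
  stopifnot(
    length(ecig_keywords) >= 1, length(promo_keywords) >= 1,
    min_support >= 1,
    min_rule_probability >= 0, min_rule_probability <= 1,
    alpha > 0, alpha < 1,
    nrow(windows) == 3, all(windows$start <= windows$end),
    age_split > 18
  )
  if (!setequal(windows$label, period_levels())) {
    rlang::abort("`windows$label` must be the three period labels.")
  }
  # pairwise disjoint windows
  w <- windows[order(windows$start), ]
  if (any(w$start[-1] <= w$end[-nrow(w)])) {
    rlang::abort("Period windows must be pairwise disjoint.")
  }
  structure(
    list(
      ecig_keywords = stringr::str_to_lower(ecig_keywords),
      promo_keywords = stringr::str_to_lower(promo_keywords),
      stopwords = stringr::str_to_lower(stopwords),
      quit_lemmas = stringr::str_to_lower(quit_lemmas),
      min_support = as.integer(min_support),
      min_rule_probability = min_rule_probability,
      alpha = alpha,
      windows = windows[match(period_levels(), windows$label), ],
      age_split = as.integer(age_split)
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  relevance keywords:", length(x$ecig_keywords), "\n")
  cat("  promo keywords:    ", length(x$promo_keywords), "\n")
  cat("  stopwords:         ", length(x$stopwords), "\n")
  cat("  quit lemmas:       ", paste(x$quit_lemmas, collapse = ", "), "\n")
  cat("  min_support:       ", x$min_support, "\n")
  cat("  min_rule_prob:     ", x$min_rule_probability, "\n")
  cat("  alpha:             ", x$alpha, "\n")
  cat("  windows:\n")
  for (i in seq_len(nrow(x$windows))) {
    cat(sprintf(
      "    %-20s %s .. %s\n", x$windows$label[i],
      x$windows$start[i], x$windows$end[i]
    ))
  }
  invisible(x)
}
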