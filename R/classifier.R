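#' Expand lexicon lemmas into morphological variants
#'
#' Deterministic suffix table standing in for "a lemma and its variants":
#' each lemma yields itself, the -s form, and -ing/-ed forms with final
#' consonant doubling after a vowel-consonant ending (quit -> quitting,
#' quitted; stop -> stopping, stopped) and e-dropping for lemmas ending in
#' "e".
#'
#' @param lemmas Character vector of lowercase lemmas.
#' @return Sorted character vector of unique variant tokens (a superset of
#'   `lemmas`).
#' @examples
#' expand_variants(c("quit", "stop"))
#' @export
expand_variants <- function(lemmas) {
  if (length(lemmas) == 0) {
    return(character())
  }
  lemmas <- stringr::str_to_lower(lemmas)
  vowels <- c("a", "e", "i", "o", "u")
  one <- function(l) {
    n <- nchar(l)
    last <- substr(l, n, n)
    prev <- if (n >= 2) substr(l, n - 1, n - 1) else ""
    if (last == "e") {
      stem <- substr(l, 1, n - 1)
      return(c(l, paste0(l, "s"), paste0(stem, "ing"), paste0(stem, "ed")))
    }
    dbl <- if (!(last %in% c(vowels, "w", "x", "y")) && prev %in% vowels) last else ""
    c(l, paste0(l, "s"), paste0(l, dbl, "ing"), paste0(l, dbl, "ed"))
  }
  sort(unique(unlist(lapply(lemmas, one))))
}

#' Quit-vaping lexicon
#'
#' Bundles the lexicon lemmas with their expanded variant set. The default
#' lemmas (`"quit"`, `"stop"`) are the outcome of the association-rule
#' lexicon derivation on the original corpus; [select_quit_keywords()]
#' re-derives them when mining is enabled.
#'
#' @param lemmas Lexicon lemmas.
#' @param extra_variants Additional variant tokens to accept verbatim.
#' @return A list of class `quit_lexicon` with elements `lemmas` and
#'   `variants`.
#' @export
quit_lexicon <- function(lemmas = c("quit", "stop"),
                         extra_variants = character()) {
  lemmas <- stringr::str_to_lower(lemmas)
  structure(
    list(
      lemmas = lemmas,
      variants = sort(unique(c(
        expand_variants(lemmas), stringr::str_to_lower(extra_variants)
      )))
    ),
    class = "quit_lexicon"
  )
}

#' @export
print.quit_lexicon <- function(x, ...) {
  cat("<quit_lexicon>", length(x$lemmas), "lemma(s),",
      length(x$variants), "variant token(s)\n")
  cat("  ", paste(x$variants, collapse = ", "), "\n")
  invisible(x)
}

#' Classify tweets as quit-vaping mentions
#'
#' A tweet mentions quitting vaping when its token set (after punctuation
#' removal and lowercasing) intersects the lexicon's variant set. No
#' co-occurring vaping token is required — the corpus is already
#' topic-filtered — and negation is not modelled.
#'
#' @param text Character vector of tweet texts (already relevance-, US- and
#'   commercial-filtered in the standard pipeline).
#' @param lexicon A [quit_lexicon()].
#' @param stopwords Stopwords removed during tokenization; variants that
#'   are themselves stopwords would be unmatchable, mirroring the mining
#'   tokenizer.
#' @return Logical vector, one element per text.
#' @examples
#' classify_quit("i quit smokin the juul 1 week ago today", quit_lexicon())
#' @export
classify_quit <- function(text, lexicon = quit_lexicon(),
                          stopwords = character()) {
  variants <- setdiff(lexicon$variants, stopwords)
  if (length(variants) == 0 || length(text) == 0) {
    return(rep(FALSE, length(text)))
  }
  # token-mode matching is exactly "tokenize(text) intersects variants"
  match_keywords(text, variants)
}

#' Label a corpus with quit-mention flags
#'
#' Adds an `is_quit` column to a tweet tibble and, when the tibble carries
#' a `period` column, attaches per-period totals as the `summary`
#' attribute.
#'
#' @param tweets Tweet tibble.
#' @param lexicon A [quit_lexicon()].
#' @param stopwords Passed to [classify_quit()].
#' @return `tweets` with a logical `is_quit` column.
#' @export
label_quit <- function(tweets, lexicon = quit_lexicon(),
                       stopwords = character()) {
  out <- dplyr::mutate(
    tweets, is_quit = classify_quit(.data$text, lexicon, stopwords)
  )
  if ("period" %in% names(out)) {
    attr(out, "summary") <- out |>
      dplyr::filter(.data$period %in% period_levels()) |>
      dplyr::count(.data$period, name = "n_total", .drop = FALSE) |>
      dplyr::left_join(
        out |>
          dplyr::filter(.data$is_quit, .data$period %in% period_levels()) |>
          dplyr::count(.data$period, name = "n_quit", .drop = FALSE),
        by = "period"
      ) |>
      dplyr::mutate(n_quit = dplyr::coalesce(.data$n_quit, 0L)) |>
      dplyr::filter(.data$period != "excluded")
  }
  out
}
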