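#' Match texts against a keyword set
#'
#' Case-insensitive keyword matching with two modes. Terms containing
#' letters or digits are matched as whole tokens after punctuation is
#' replaced by spaces (multi-word or hyphenated terms become token phrases,
#' so `"e-cig"` matches "my e-cig broke" and `"deal"` does not fire inside
#' "dealer"). Terms with no alphanumeric content (`"$"`, `"%"`) are matched
#' as raw substrings anywhere in the text.
#'
#' @param text Character vector of tweet texts.
#' @param keywords Character vector of lowercase keywords.
#' @return Logical vector, one element per text.
#' @examples
#' match_keywords("Get 20% off all vape pods", promo_keywords())
#' match_keywords("the dealer quit", c("deal"))
#' @export
match_keywords <- function(text, keywords) {
  if (length(text) == 0) {
    return(logical())
  }
  keywords <- stringr::str_to_lower(keywords)
  token_mode <- stringr::str_detect(keywords, "[\\p{L}\\p{N}]")
  hit <- rep(FALSE, length(text))

  if (any(token_mode)) {
    padded <- paste0(" ", normalize_text(text), " ")
    for (term in normalize_text(keywords[token_mode])) {
      hit <- hit | stringr::str_detect(
        padded, stringr::fixed(paste0(" ", term, " "))
      )
    }
  }
  if (any(!token_mode)) {
    lowered <- stringr::str_to_lower(text)
    for (term in keywords[!token_mode]) {
      hit <- hit | stringr::str_detect(lowered, stringr::fixed(term))
    }
  }
  hit[is.na(hit)] <- FALSE
  hit
}

filter_with_count <- function(tweets, keep) {
  keep[is.na(keep)] <- FALSE
  out <- tweets[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Corpus filters: topic relevance, US geolocation, commercial posts
#'
#' Pure per-tweet filters reproducing the corpus preprocessing: keep tweets
#' mentioning an e-cigarette keyword (`filter_relevant`), keep tweets whose
#' `country_code` is `"US"` — a missing country is conservatively dropped —
#' (`filter_us`), and remove commercial/promotional posts matching a
#' promotion keyword (`filter_commercial`). Each filter preserves order, is
#' idempotent, and records how many tweets it removed in the `n_removed`
#' attribute of the result.
#'
#' @param tweets Tweet tibble.
#' @param keywords Keyword vector; defaults to the study lists.
#' @return The kept tweets, with attribute `n_removed`.
#' @export
filter_relevant <- function(tweets, keywords = ecig_keywords()) {
  filter_with_count(tweets, match_keywords(tweets$text, keywords))
}

#' @rdname filter_relevant
#' @export
filter_us <- function(tweets) {
  filter_with_count(tweets, !is.na(tweets$country_code) & tweets$country_code == "US")
}

#' @rdname filter_relevant
#' @export
filter_commercial <- function(tweets, keywords = promo_keywords()) {
  filter_with_count(tweets, !match_keywords(tweets$text, keywords))
}

#' Assign tweets to policy periods
#'
#' Maps each timestamp to the period window containing its UTC calendar
#' date (both window ends inclusive), or to `"excluded"` when it falls in
#' no window — in the default study this excludes August-December 2019 and
#' anything outside June 2019 - October 2020.
#'
#' @param created_at POSIXct (or Date) vector.
#' @param windows Window tibble as from [default_windows()].
#' @return Factor with levels pre_announcement, between,
#'   post_implementation, excluded.
#' @examples
#' assign_period(as.POSIXct("2020-01-15 12:00:00", tz = "UTC"))
#' @export
assign_period <- function(created_at, windows = default_windows()) {
  date <- as.Date(created_at, tz = "UTC")
  out <- rep("excluded", length(date))
  for (i in seq_len(nrow(windows))) {
    inside <- !is.na(date) & date >= windows$start[i] & date <= windows$end[i]
    out[inside] <- windows$label[i]
  }
  factor(out, levels = c(period_levels(), "excluded"))
}
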