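# Shared fixtures and the independent brute-force mining oracle.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_tweets <- function(text,
                        created_at = "2020-01-15T12:00:00Z",
                        country_code = "US",
                        user_id = NULL,
                        tweet_id = NULL) {
  n <- length(text)
  tibble::tibble(
    tweet_id = tweet_id %||% sprintf("t%03d", seq_len(n)),
    user_id = user_id %||% sprintf("u%03d", seq_len(n)),
    created_at = as.POSIXct(
      rep_len(created_at, n),
      format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"
    ),
    text = text,
    country_code = rep_len(country_code, n),
    has_profile_face = NA
  )
}

# Exhaustive subset enumeration via bitmasks: the oracle FP-growth must
# match exactly (itemsets and supports). Only viable for <= ~14 items.
brute_force_itemsets <- function(transactions, min_support) {
  items <- sort(unique(unlist(transactions)))
  stopifnot(length(items) <= 14)
  masks <- vapply(transactions, function(t) {
    sum(bitwShiftL(1L, match(unique(t), items) - 1L))
  }, integer(1))
  out <- character()
  supp <- numeric()
  for (s in seq_len(bitwShiftL(1L, length(items)) - 1L)) {
    cnt <- sum(bitwAnd(masks, s) == s)
    if (cnt >= min_support) {
      members <- items[bitwAnd(bitwShiftL(1L, seq_along(items) - 1L), s) != 0L]
      out <- c(out, paste(members, collapse = " "))
      supp <- c(supp, cnt)
    }
  }
  sort_by_name(stats::setNames(supp, out))
}

sort_by_name <- function(x) x[order(names(x))]

# canonical named-support form of a mine_frequent_itemsets() result
canonical_itemsets <- function(tbl) {
  sort_by_name(stats::setNames(
    tbl$support,
    vapply(tbl$items, paste, character(1), collapse = " ")
  ))
}

random_transactions <- function(n_trans, n_items) {
  items <- letters[seq_len(n_items)]
  lapply(seq_len(n_trans), function(i) {
    sample(items, sample.int(n_items, 1))
  })
}
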