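#' Simulate a corpus to disk
#'
#' Generates a synthetic corpus and writes the artifacts a real run would
#' ingest: the JSONL corpus, the demographics CSV, per-tweet and per-user
#' ground-truth CSVs, and a JSON run manifest. Byte-identical across reruns
#' with the same configuration.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if absent).
#' @param seed Optional seed overriding `config$seed`.
#' @return Named list of written paths, invisibly.
#' @export
simulate_corpus <- function(config = generator_config(), out_dir,
                            seed = NULL) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_corpus(config)
  paths <- list(
    corpus = file.path(out_dir, "corpus.jsonl"),
    demographics = file.path(out_dir, "demographics.csv"),
    truth_tweets = file.path(out_dir, "truth_tweets.csv"),
    truth_users = file.path(out_dir, "truth_users.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_tweets_jsonl(corpus$tweets, paths$corpus)
  readr::write_csv(corpus$demographics, paths$demographics)
  readr::write_csv(corpus$truth$tweets, paths$truth_tweets)
  readr::write_csv(corpus$truth$users, paths$truth_users)
  manifest <- list(
    stage = "simulate",
    seed = config$seed,
    n_tweets = nrow(corpus$tweets),
    n_users = nrow(corpus$truth$users),
    n_quit_tweets = sum(corpus$truth$tweets$is_quit),
    n_inferable_users = nrow(corpus$demographics),
    outputs = unlist(paths[setdiff(names(paths), "manifest")])
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Run the full quit-vaping analysis
#'
#' End-to-end pipeline on a tweet corpus: topic-relevance filter, US
#' geolocation filter, commercial-post removal, assignment to the three
#' policy windows (out-of-window tweets excluded), optional re-derivation
#' of the quit lexicon by FP-growth association-rule mining, quit-mention
#' labelling, per-period tweet and unique-user tabulation, pairwise
#' two-proportion z-tests, and (when demographics are supplied) gender and
#' age-group breakdowns of quit mentioners.
#'
#' @param tweets Tweet tibble, or path to a JSONL corpus.
#' @param demographics Optional demographics tibble or CSV path.
#' @param config A [study_config()].
#' @param mine_lexicon If `TRUE`, derive the lexicon from the corpus via
#'   [mine_frequent_itemsets()] / [select_quit_keywords()] (falling back to
#'   `config$quit_lemmas` if nothing passes the thresholds); if `FALSE`
#'   (default) use `config$quit_lemmas` verbatim.
#' @param first_mention_only Passed to [tabulate_periods()].
#' @param quiet Suppress per-stage log messages.
#' @return An object of class `vape_analysis`: per-period `counts`,
#'   pairwise `comparisons`, optional `demographics` breakdown, the
#'   `lexicon` used, a stage-count `manifest`, and the labelled tweets.
#' @examples
#' corpus <- generate_corpus(generator_config(
#'   users_per_period = c(300, 300, 300), quit_rate = 0.05
#' ))
#' fit <- run_analysis(corpus$tweets, corpus$demographics, quiet = TRUE)
#' tidy(fit)
#' @export
run_analysis <- function(tweets, demographics = NULL,
                         config = study_config(), mine_lexicon = FALSE,
                         first_mention_only = FALSE, quiet = FALSE) {
  log_stage <- function(...) {
    if (!quiet) rlang::inform(sprintf(...))
  }
  if (is.character(tweets)) {
    tweets <- read_tweets_jsonl(tweets)
  }
  if (is.character(demographics)) {
    demographics <- read_demographics(demographics)
  }
  manifest <- list(n_read = nrow(tweets), timestamp = format(Sys.time(), tz = "UTC"))

  kept <- filter_relevant(tweets, config$ecig_keywords)
  manifest$n_removed_irrelevant <- attr(kept, "n_removed")
  log_stage(
    "relevance filter: %d read, %d kept, %d removed",
    manifest$n_read, nrow(kept), manifest$n_removed_irrelevant
  )
  kept <- filter_us(kept)
  manifest$n_removed_non_us <- attr(kept, "n_removed")
  log_stage("US filter: %d kept, %d removed", nrow(kept), manifest$n_removed_non_us)
  kept <- filter_commercial(kept, config$promo_keywords)
  manifest$n_removed_commercial <- attr(kept, "n_removed")
  log_stage(
    "commercial filter: %d kept, %d removed",
    nrow(kept), manifest$n_removed_commercial
  )
  kept <- dplyr::mutate(
    kept, period = assign_period(.data$created_at, config$windows)
  )
  manifest$n_excluded_window <- sum(kept$period == "excluded")
  kept <- dplyr::filter(kept, .data$period != "excluded")
  manifest$n_analyzed <- nrow(kept)
  log_stage(
    "window assignment: %d in-period, %d excluded",
    manifest$n_analyzed, manifest$n_excluded_window
  )
  if (nrow(kept) == 0) {
    rlang::abort("No relevant tweets remain after filtering.")
  }

  if (mine_lexicon) {
    transactions <- tokenize_transactions(kept$text, config$stopwords)
    itemsets <- mine_frequent_itemsets(transactions, config$min_support)
    rules <- derive_pair_rules(itemsets)
    lemmas <- select_quit_keywords(
      rules,
      min_support = config$min_support,
      min_rule_probability = config$min_rule_probability
    )
    if (length(lemmas) == 0) {
      log_stage("mining selected no keywords; falling back to config lemmas")
      lemmas <- config$quit_lemmas
    }
    lexicon <- quit_lexicon(lemmas)
    manifest$mined_lemmas <- lemmas
  } else {
    lexicon <- quit_lexicon(config$quit_lemmas)
  }

  kept <- label_quit(kept, lexicon)
  manifest$n_quit <- sum(kept$is_quit)
  log_stage("quit classifier: %d of %d labelled quit", manifest$n_quit, nrow(kept))

  counts <- tabulate_periods(kept, first_mention_only = first_mention_only)
  comparisons <- compare_periods(counts, alpha = config$alpha)
  demo <- NULL
  if (!is.null(demographics)) {
    quit_users <- kept |>
      dplyr::filter(.data$is_quit) |>
      dplyr::distinct(.data$period, .data$user_id)
    demo <- demographic_breakdown(
      quit_users, demographics,
      age_split = config$age_split, alpha = config$alpha
    )
  }
  structure(
    list(
      counts = counts, comparisons = comparisons, demographics = demo,
      lexicon = lexicon, manifest = manifest, config = config,
      tweets = kept
    ),
    class = "vape_analysis"
  )
}

#' @export
print.vape_analysis <- function(x, ...) {
  cat("<vape_analysis>\n")
  cat(sprintf(
    "  %d tweets analysed (%d quit mentions) across %d periods\n",
    sum(x$counts$n_tweets), sum(x$counts$n_quit_tweets), nrow(x$counts)
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy / summarise a fitted analysis
#'
#' `tidy()` returns one row per period with counts and half-up-rounded
#' percentages at the tweet and unique-user level; `glance()` returns the
#' pooled totals plus the pre-vs-post z-tests.
#'
#' @param x A `vape_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.vape_analysis <- function(x, ...) {
  x$counts |>
    dplyr::mutate(
      tweet_pct = proportion_pct(.data$n_quit_tweets, pmax(.data$n_tweets, 1)),
      user_pct = proportion_pct(.data$n_quit_users, pmax(.data$n_users, 1))
    )
}

#' @rdname tidy.vape_analysis
#' @export
glance.vape_analysis <- function(x, ...) {
  pp <- x$comparisons |>
    dplyr::filter(
      .data$group1 == "pre_announcement",
      .data$group2 == "post_implementation"
    )
  tibble::tibble(
    n_tweets = sum(x$counts$n_tweets),
    n_quit_tweets = sum(x$counts$n_quit_tweets),
    n_users = sum(x$counts$n_users),
    n_quit_users = sum(x$counts$n_quit_users),
    z_tweets_pre_post = pp$statistic[pp$unit == "tweets"],
    p_tweets_pre_post = pp$p.value[pp$unit == "tweets"],
    z_users_pre_post = pp$statistic[pp$unit == "users"],
    p_users_pre_post = pp$p.value[pp$unit == "users"]
  )
}

#' @export
summary.vape_analysis <- function(object, ...) {
  x <- object
  cat("Quit-vaping mentions by policy period\n")
  cat("=====================================\n")
  td <- tidy(x)
  for (i in seq_len(nrow(td))) {
    cat(sprintf(
      "  %-20s tweets %5d/%-7d (%5.2f%%)   users %5d/%-7d (%5.2f%%)\n",
      td$period[i], td$n_quit_tweets[i], td$n_tweets[i], td$tweet_pct[i],
      td$n_quit_users[i], td$n_users[i], td$user_pct[i]
    ))
  }
  cat("\nPairwise two-proportion z-tests\n")
  cmp <- x$comparisons
  for (i in seq_len(nrow(cmp))) {
    stars <- dplyr::case_when(
      cmp$p.value[i] < 0.001 ~ "***",
      cmp$p.value[i] < 0.01 ~ "**",
      cmp$p.value[i] < x$config$alpha ~ "*",
      TRUE ~ ""
    )
    cat(sprintf(
      "  [%-6s] %s vs %s: z = %6.2f, p = %s %s\n",
      cmp$unit[i], cmp$group1[i], cmp$group2[i], cmp$statistic[i],
      format.pval(cmp$p.value[i], digits = 3), stars
    ))
  }
  if (!is.null(x$demographics)) {
    cat("\n")
    print(x$demographics)
  }
  invisible(x)
}

#' Write analysis result tables
#'
#' Serialises a fitted analysis to CSV result tables (per-period counts
#' with percentages, pairwise comparisons, demographic breakdown and tests
#' when present) plus a JSON manifest of per-stage record counts.
#'
#' @param analysis A `vape_analysis` object.
#' @param out_dir Output directory (created if absent).
#' @return Named list of written paths, invisibly.
#' @export
write_results <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "vape_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    counts = file.path(out_dir, "period_counts.csv"),
    comparisons = file.path(out_dir, "comparisons.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_counts_csv(tidy(analysis), paths$counts)
  readr::write_csv(analysis$comparisons, paths$comparisons)
  if (!is.null(analysis$demographics)) {
    paths$demographics <- file.path(out_dir, "demographics_breakdown.csv")
    paths$demographic_tests <- file.path(out_dir, "demographics_tests.csv")
    readr::write_csv(analysis$demographics$breakdown, paths$demographics)
    readr::write_csv(analysis$demographics$tests, paths$demographic_tests)
  }
  jsonlite::write_json(
    analysis$manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
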