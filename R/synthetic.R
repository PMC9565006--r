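# Template vocabulary for the generator. Filler words are disjoint, by
# construction, from every promotion keyword, quit-lexicon variant and "$"/
# "%", so only tweets deliberately rendered as commercial/quit can trip
# those matchers.
sim_vocab <- function() {
  list(
    ecig = c("vape", "vaping", "juul", "ecig", "vapes", "ejuice", "eliquid"),
    fillers = c(
      "today", "week", "ago", "finally", "honestly", "really", "still",
      "love", "hate", "miss", "craving", "lungs", "health", "better",
      "feel", "good", "bad", "one", "two", "three", "day", "month",
      "year", "since", "trying", "life", "mint", "mango", "pen", "pod",
      "mod", "coil", "juice", "tank", "battery", "cloud", "nicotine",
      "buzz", "morning", "coffee", "friend", "again", "never", "always",
      "maybe", "thinking", "started", "last"
    ),
    promo = c(
      "sale", "discount", "promo", "deal", "offer", "save", "store",
      "price", "wholesale", "sell"
    ),
    countries = c("GB", "CA", "AU", "DE", "FR", "NZ", "IE")
  )
}

#' Render synthetic tweet texts
#'
#' Draws template-based texts of a given kind: `"plain"` texts contain an
#' e-cigarette keyword plus neutral filler words; `"quit"` texts
#' additionally embed a quit-lexicon variant; `"commercial"` texts embed a
#' promotion keyword. Texts are 3-40 tokens long. Uses the current RNG
#' state (seed at the call site for reproducibility).
#'
#' @param kind One of `"plain"`, `"quit"`, `"commercial"`.
#' @param n Number of texts to draw.
#' @param quit_terms Pool of quit tokens used for `kind = "quit"`; defaults
#'   to the default lexicon variants. Supplying out-of-lexicon synonyms
#'   (e.g. `"ditching"`) creates negative controls for classifier recall.
#' @return Character vector of length `n`.
#' @examples
#' set.seed(1)
#' render_text("quit", 3)
#' @export
render_text <- function(kind = c("plain", "quit", "commercial"), n = 1,
                        quit_terms = expand_variants(c("quit", "stop"))) {
  kind <- rlang::arg_match(kind)
  if (n == 0) {
    return(character())
  }
  voc <- sim_vocab()
  n_fill <- sample(3:8, n, replace = TRUE)
  fill <- sample(voc$fillers, sum(n_fill), replace = TRUE)
  base <- vapply(
    split(fill, rep.int(seq_len(n), n_fill)), paste, character(1),
    collapse = " "
  )
  ecig <- sample(voc$ecig, n, replace = TRUE)
  extra <- switch(kind,
    plain = character(n),
    quit = sample(quit_terms, n, replace = TRUE),
    commercial = sample(voc$promo, n, replace = TRUE)
  )
  extra[is.na(extra)] <- ""
  # randomise where the marked terms sit relative to the filler run
  swap <- stats::runif(n) < 0.5
  a <- ifelse(swap, ecig, extra)
  b <- ifelse(swap, extra, ecig)
  pos <- sample(3, n, replace = TRUE)
  out <- dplyr::case_when(
    pos == 1 ~ paste(a, b, base),
    pos == 2 ~ paste(a, base, b),
    TRUE ~ paste(base, a, b)
  )
  stringr::str_squish(out)
}

#' Generator configuration
#'
#' Study conditions for the synthetic corpus. Defaults are scaled to one
#' tenth of the original corpus: per-period user counts are the user
#' denominators / 10, and the zero-truncated-Poisson tweets-per-user means
#' are set so expected per-period tweet counts match the tweet denominators
#' / 10; per-period quit rates default to the observed
#' 0.11%/0.20%/0.24%-scale values. Margins the study does not report
#' (commercial and non-US fractions, gender/age mix of the full corpus)
#' are documented assumptions, not estimates.
#'
#' @param users_per_period Integer vector (pre, between, post) of user
#'   counts.
#' @param tweets_per_user Mean tweets per user per period (zero-truncated
#'   Poisson; each mean must exceed 1). Length 1 or 3.
#' @param quit_rate Per-period probability that a non-commercial tweet
#'   mentions quitting.
#' @param commercial_fraction Probability a tweet is commercial.
#' @param non_us_fraction Probability a user is located outside the US.
#' @param female_fraction Probability a user is female.
#' @param young_fraction Probability a user's age lies in `[18, 35)`; the
#'   rest are uniform on `[35, 70]`.
#' @param demographics_inferable_rate Probability a user's profile image
#'   yields a usable (single-face) age/gender inference.
#' @param seed Integer RNG seed; corpora are byte-identical for equal
#'   seeds.
#' @param windows Period windows tibble.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(users_per_period = c(12674L, 4837L, 18969L),
                             tweets_per_user = c(1.308, 3.502, 3.648),
                             quit_rate = c(0.0011, 0.0020, 0.0024),
                             commercial_fraction = 0.25,
                             non_us_fraction = 0.35,
                             female_fraction = 0.40,
                             young_fraction = 0.80,
                             demographics_inferable_rate = 0.1024,
                             seed = 1L,
                             windows = default_windows()) {
  users_per_period <- as.integer(rep_len(users_per_period, 3))
  tweets_per_user <- rep_len(tweets_per_user, 3)
  quit_rate <- rep_len(quit_rate, 3)
  fracs <- c(
    quit_rate, commercial_fraction, non_us_fraction, female_fraction,
    young_fraction, demographics_inferable_rate
  )
  stopifnot(
    all(users_per_period >= 0), sum(users_per_period) >= 1,
    all(tweets_per_user > 1),
    all(fracs >= 0), all(fracs <= 1),
    nrow(windows) == 3
  )
  structure(
    list(
      users_per_period = users_per_period,
      tweets_per_user = tweets_per_user,
      quit_rate = quit_rate,
      commercial_fraction = commercial_fraction,
      non_us_fraction = non_us_fraction,
      female_fraction = female_fraction,
      young_fraction = young_fraction,
      demographics_inferable_rate = demographics_inferable_rate,
      seed = as.integer(seed),
      windows = windows
    ),
    class = "generator_config"
  )
}

# zero-truncated Poisson: solve lambda from the truncated mean, then draw
# by inverse CDF restricted to X >= 1
ztp_lambda <- function(mean) {
  stats::uniroot(
    function(l) l / (1 - exp(-l)) - mean,
    lower = 1e-9, upper = max(10 * mean, 2), tol = 1e-10
  )$root
}

rztpois <- function(n, mean) {
  if (n == 0) {
    return(integer())
  }
  lambda <- ztp_lambda(mean)
  u <- stats::runif(n, exp(-lambda), 1)
  as.integer(stats::qpois(u, lambda))
}

#' Generate a synthetic tweet corpus with ground truth
#'
#' Emulates the structure the analysis assumes: every tweet contains an
#' e-cigarette keyword (keyword-based collection), each user belongs to one
#' period and posts a zero-truncated-Poisson number of tweets with
#' timestamps uniform in that period's window, tweets are independently
#' commercial with probability `commercial_fraction`, non-commercial tweets
#' mention quitting with the period's `quit_rate`, users are non-US with
#' probability `non_us_fraction` (their tweets carry a non-US country
#' code), and the demographics table contains exactly the inferable users
#' with their true age and gender. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param quit_terms Token pool for quit tweets; the default (the default
#'   lexicon variants) makes classifier precision and recall exactly 1
#'   against ground truth.
#' @return A list of class `vape_corpus`: `tweets` (corpus tibble),
#'   `demographics` (inferable users), `truth` (list of per-tweet and
#'   per-user ground-truth tibbles) and `config`.
#' @export
generate_corpus <- function(config = generator_config(),
                            quit_terms = expand_variants(c("quit", "stop"))) {
  stopifnot(inherits(config, "generator_config"))
  if (sum(config$users_per_period) < 1) {
    rlang::abort("Generator needs at least one user in some period.")
  }
  voc <- sim_vocab()
  withr::with_seed(config$seed, {
    users <- purrr::map_dfr(1:3, function(p) {
      n_u <- config$users_per_period[p]
      if (n_u == 0) {
        return(tibble::tibble())
      }
      young <- stats::runif(n_u) < config$young_fraction
      tibble::tibble(
        user_id = sprintf("u%d_%06d", p, seq_len(n_u)),
        period = period_levels()[p],
        period_idx = p,
        age = as.integer(ifelse(
          young,
          floor(stats::runif(n_u, 18, 35)),
          floor(stats::runif(n_u, 35, 71))
        )),
        gender = ifelse(
          stats::runif(n_u) < config$female_fraction, "female", "male"
        ),
        is_us = stats::runif(n_u) >= config$non_us_fraction,
        inferable = stats::runif(n_u) < config$demographics_inferable_rate,
        n_tweets = rztpois(n_u, config$tweets_per_user[p])
      )
    })

    tw <- users[rep(seq_len(nrow(users)), users$n_tweets), ] |>
      dplyr::select("user_id", "period", "period_idx", "is_us", "inferable")
    n_tw <- nrow(tw)
    win <- config$windows[match(tw$period, config$windows$label), ]
    t0 <- as.numeric(as.POSIXct(paste(win$start, "00:00:00"), tz = "UTC"))
    t1 <- as.numeric(as.POSIXct(paste(win$end, "23:59:59"), tz = "UTC"))
    created <- as.POSIXct(
      floor(stats::runif(n_tw, t0, t1)),
      origin = "1970-01-01", tz = "UTC"
    )
    is_commercial <- stats::runif(n_tw) < config$commercial_fraction
    is_quit <- !is_commercial &
      stats::runif(n_tw) < config$quit_rate[tw$period_idx]
    kind <- dplyr::case_when(
      is_commercial ~ "commercial",
      is_quit ~ "quit",
      TRUE ~ "plain"
    )
    text <- character(n_tw)
    for (k in c("plain", "quit", "commercial")) {
      idx <- which(kind == k)
      text[idx] <- render_text(k, length(idx), quit_terms = quit_terms)
    }
    country <- ifelse(
      tw$is_us, "US",
      sample(voc$countries, n_tw, replace = TRUE)
    )
    ord <- order(created, method = "radix")
    tweets <- tibble::tibble(
      tweet_id = as.character(sample.int(.Machine$integer.max - 1L, n_tw)),
      user_id = tw$user_id,
      created_at = created,
      text = text,
      country_code = country,
      has_profile_face = tw$inferable
    )[ord, ]
    truth_tweets <- tibble::tibble(
      tweet_id = tweets$tweet_id,
      user_id = tw$user_id[ord],
      period = tw$period[ord],
      is_quit = is_quit[ord],
      is_commercial = is_commercial[ord],
      is_us = tw$is_us[ord]
    )
    demographics <- users |>
      dplyr::filter(.data$inferable) |>
      dplyr::transmute(
        user_id = .data$user_id, age = .data$age, gender = .data$gender,
        face_valid = TRUE
      )
    truth_users <- users |>
      dplyr::select(
        "user_id", "period", "age", "gender", "is_us", "inferable",
        "n_tweets"
      )
    structure(
      list(
        tweets = tweets, demographics = demographics,
        truth = list(tweets = truth_tweets, users = truth_users),
        config = config
      ),
      class = "vape_corpus"
    )
  })
}

#' @export
print.vape_corpus <- function(x, ...) {
  cat("<vape_corpus>\n")
  cat("  tweets:      ", nrow(x$tweets), "\n")
  cat("  users:       ", nrow(x$truth$users), "\n")
  cat("  quit tweets: ", sum(x$truth$tweets$is_quit), "\n")
  cat("  inferable:   ", nrow(x$demographics), "\n")
  invisible(x)
}
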