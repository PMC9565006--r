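#' Percentage with half-up rounding
#'
#' `100 * x / n` rounded half-up to two decimals, the convention used for
#' every reported proportion (e.g. 1644 of 691,979 tweets -> 0.24).
#'
#' @param x Numerator count(s).
#' @param n Denominator count(s), positive.
#' @return Numeric percentage(s) rounded to 2 decimals.
#' @examples
#' proportion_pct(1644, 691979)
#' proportion_pct(16, 39)
#' @export
proportion_pct <- function(x, n) {
  assert_counts(x, n)
  round_half_up(100 * x / n, 2)
}

#' Two-proportion z-test
#'
#' Normal-approximation test of equality of two binomial proportions using
#' the pooled variance estimate:
#' \deqn{z = (p_2 - p_1) / \sqrt{\hat p (1 - \hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p = (x_1 + x_2)/(n_1 + n_2)} and a two-sided p-value from
#' the standard normal. When the pooled proportion is 0 or 1 the statistic
#' is degenerate; z is defined as 0 and p as 1, with a warning.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param alpha Two-sided significance level (default 0.05).
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `two_prop_ztest`; see [tidy.two_prop_ztest()].
#' @examples
#' two_proportion_ztest(189, 165782, 1644, 691979)
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2, alpha = 0.05,
                                 labels = c("group1", "group2")) {
  assert_counts(c(x1, x2), c(n1, n2))
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    rlang::warn("Pooled proportion is 0 or 1; z set to 0 and p to 1.")
    z <- 0
    p_value <- 1
  } else {
    se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    z <- (x2 / n2 - x1 / n1) / se
    p_value <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(
      labels = labels,
      x1 = x1, n1 = n1, x2 = x2, n2 = n2,
      p1 = x1 / n1, p2 = x2 / n2,
      z = z, p_value = p_value,
      alpha = alpha, significant = p_value < alpha
    ),
    class = "two_prop_ztest"
  )
}

#' @export
print.two_prop_ztest <- function(x, ...) {
  cat("Two-proportion z-test (pooled)\n")
  cat(sprintf(
    "  %s: %d/%d (%.2f%%)   %s: %d/%d (%.2f%%)\n",
    x$labels[1], x$x1, x$n1, 100 * x$p1,
    x$labels[2], x$x2, x$n2, 100 * x$p2
  ))
  cat(sprintf(
    "  z = %.3f, two-sided p = %s%s\n",
    x$z, format.pval(x$p_value, digits = 3),
    if (x$significant) sprintf("  (significant at alpha = %g)", x$alpha) else ""
  ))
  invisible(x)
}

#' Tidy a two-proportion z-test
#'
#' @param x A `two_prop_ztest` object.
#' @param ... Unused.
#' @return A one-row tibble with the counts, proportions, statistic and
#'   p-value (`tidy`), or the statistic-level summary (`glance`).
#' @export
tidy.two_prop_ztest <- function(x, ...) {
  tibble::tibble(
    group1 = x$labels[1], group2 = x$labels[2],
    x1 = x$x1, n1 = x$n1, x2 = x$x2, n2 = x$n2,
    p1 = x$p1, p2 = x$p2,
    estimate = x$p2 - x$p1,
    statistic = x$z, p.value = x$p_value,
    significant = x$significant
  )
}

#' @rdname tidy.two_prop_ztest
#' @export
glance.two_prop_ztest <- function(x, ...) {
  tibble::tibble(
    statistic = x$z, p.value = x$p_value, alpha = x$alpha,
    significant = x$significant
  )
}

#' Tabulate per-period tweet and unique-user quit counts
#'
#' Counts, for each policy period: tweets, quit-labelled tweets, unique
#' users, and unique users with at least one quit-labelled tweet in that
#' period. Users active in several periods contribute to each period's
#' denominator. With `first_mention_only = TRUE` a user's quit mentions are
#' credited only to the earliest period in which they mention quitting, so
#' per-period quit-user counts sum to the number of distinct quit
#' mentioners.
#'
#' @param tweets Tweet tibble carrying `user_id`, `period` (from
#'   [assign_period()]) and `is_quit` (from [label_quit()]); rows with
#'   period `"excluded"` are ignored.
#' @param first_mention_only Credit each quit user only to their first
#'   quit period (default FALSE: per-period counting).
#' @return A tibble with one row per period: `period`, `n_tweets`,
#'   `n_quit_tweets`, `n_users`, `n_quit_users`.
#' @export
tabulate_periods <- function(tweets, first_mention_only = FALSE) {
  stopifnot(all(c("user_id", "period", "is_quit") %in% names(tweets)))
  tw <- tweets |>
    dplyr::filter(.data$period %in% period_levels()) |>
    dplyr::mutate(period = factor(.data$period, levels = period_levels()))
  base <- tw |>
    dplyr::group_by(.data$period, .drop = FALSE) |>
    dplyr::summarise(
      n_tweets = dplyr::n(),
      n_quit_tweets = sum(.data$is_quit),
      n_users = dplyr::n_distinct(.data$user_id),
      .groups = "drop"
    )
  quit_users <- tw |>
    dplyr::filter(.data$is_quit) |>
    dplyr::distinct(.data$period, .data$user_id)
  if (first_mention_only && nrow(quit_users) > 0) {
    quit_users <- quit_users |>
      dplyr::mutate(ord = as.integer(.data$period)) |>
      dplyr::group_by(.data$user_id) |>
      dplyr::slice_min(.data$ord, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-"ord")
  }
  qu <- quit_users |>
    dplyr::count(.data$period, name = "n_quit_users", .drop = FALSE)
  base |>
    dplyr::left_join(qu, by = "period") |>
    dplyr::mutate(
      n_quit_users = as.integer(dplyr::coalesce(.data$n_quit_users, 0L)),
      period = as.character(.data$period)
    )
}

#' Pairwise period comparisons of quit proportions
#'
#' Runs the pooled two-proportion z-test between every pair of periods, at
#' both the tweet level (quit tweets / tweets) and the unique-user level
#' (quit users / users).
#'
#' @param counts Per-period counts from [tabulate_periods()].
#' @param alpha Significance level.
#' @return A tibble with one row per (unit, period pair): counts,
#'   percentages (half-up, 2 decimals), z, p-value and significance.
#' @export
compare_periods <- function(counts, alpha = 0.05) {
  counts <- counts[match(period_levels(), counts$period), ]
  pairs <- utils::combn(period_levels(), 2, simplify = FALSE)
  units <- list(
    tweets = c("n_quit_tweets", "n_tweets"),
    users = c("n_quit_users", "n_users")
  )
  out <- purrr::map_dfr(names(units), function(u) {
    xcol <- units[[u]][1]
    ncol <- units[[u]][2]
    purrr::map_dfr(pairs, function(pr) {
      i <- match(pr[1], counts$period)
      j <- match(pr[2], counts$period)
      if (counts[[ncol]][i] == 0 || counts[[ncol]][j] == 0) {
        return(tibble::tibble())  # empty period: no comparison possible
      }
      zt <- two_proportion_ztest(
        counts[[xcol]][i], counts[[ncol]][i],
        counts[[xcol]][j], counts[[ncol]][j],
        alpha = alpha, labels = pr
      )
      dplyr::mutate(tidy(zt), unit = u, .before = 1)
    })
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(
      unit = character(), group1 = character(), group2 = character(),
      x1 = numeric(), n1 = numeric(), x2 = numeric(), n2 = numeric(),
      p1 = numeric(), p2 = numeric(), estimate = numeric(),
      statistic = numeric(), p.value = numeric(), significant = logical(),
      pct1 = numeric(), pct2 = numeric()
    ))
  }
  dplyr::mutate(
    out,
    pct1 = proportion_pct(.data$x1, .data$n1),
    pct2 = proportion_pct(.data$x2, .data$n2)
  )
}

#' Demographic breakdown of quit mentioners
#'
#' Joins the per-period quit users to the inferred demographics table and
#' summarises gender and age-group composition. Only records with
#' `face_valid = TRUE` and inferred age >= 18 are usable; the young bin is
#' `[18, age_split)` and age `age_split` and above is the old bin. Pairwise
#' pooled z-tests compare the female and young shares between periods.
#'
#' @param quit_users Tibble with columns `period`, `user_id` — one row per
#'   quit-mentioning user per period (e.g. from [run_analysis()]
#'   internals, or built directly).
#' @param demographics Demographics tibble from [read_demographics()].
#' @param age_split Young/old boundary in years (default 35; age 35 falls
#'   in the old bin).
#' @param alpha Significance level for the pairwise tests.
#' @return A list of class `demographic_breakdown` with `breakdown` (one
#'   row per period: `n_quit_users`, `n_inferred`, `n_female`, `n_young`,
#'   `female_pct`, `young_pct` — percentages are `NA` where `n_inferred`
#'   is 0) and `tests` (pairwise z-tests for the female and young shares).
#' @export
demographic_breakdown <- function(quit_users, demographics,
                                  age_split = 35, alpha = 0.05) {
  usable <- demographics |>
    dplyr::select("user_id", "age", "gender", "face_valid") |>
    dplyr::filter(.data$face_valid, .data$age >= 18) |>
    dplyr::distinct(.data$user_id, .keep_all = TRUE)
  joined <- quit_users |>
    dplyr::distinct(.data$period, .data$user_id) |>
    dplyr::mutate(period = factor(.data$period, levels = period_levels())) |>
    dplyr::left_join(usable, by = "user_id")
  breakdown <- joined |>
    dplyr::group_by(.data$period, .drop = FALSE) |>
    dplyr::summarise(
      n_quit_users = dplyr::n(),
      n_inferred = sum(!is.na(.data$age)),
      n_female = sum(.data$gender == "female", na.rm = TRUE),
      n_young = sum(.data$age < age_split, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      female_pct = ifelse(
        .data$n_inferred > 0,
        proportion_pct(.data$n_female, pmax(.data$n_inferred, 1)), NA_real_
      ),
      young_pct = ifelse(
        .data$n_inferred > 0,
        proportion_pct(.data$n_young, pmax(.data$n_inferred, 1)), NA_real_
      ),
      period = as.character(.data$period)
    )
  pairs <- utils::combn(period_levels(), 2, simplify = FALSE)
  measures <- list(female = "n_female", young = "n_young")
  tests <- purrr::map_dfr(names(measures), function(m) {
    xcol <- measures[[m]]
    purrr::map_dfr(pairs, function(pr) {
      i <- match(pr[1], breakdown$period)
      j <- match(pr[2], breakdown$period)
      if (breakdown$n_inferred[i] == 0 || breakdown$n_inferred[j] == 0) {
        return(tibble::tibble())
      }
      zt <- two_proportion_ztest(
        breakdown[[xcol]][i], breakdown$n_inferred[i],
        breakdown[[xcol]][j], breakdown$n_inferred[j],
        alpha = alpha, labels = pr
      )
      dplyr::mutate(tidy(zt), measure = m, .before = 1)
    })
  })
  structure(
    list(breakdown = breakdown, tests = tests, age_split = age_split),
    class = "demographic_breakdown"
  )
}

#' @export
print.demographic_breakdown <- function(x, ...) {
  cat("Demographics of quit-vaping mentioners (inferable users only)\n")
  print(x$breakdown)
  if (nrow(x$tests) > 0) {
    cat("Pairwise comparisons:\n")
    print(dplyr::select(
      x$tests, "measure", "group1", "group2", "statistic", "p.value",
      "significant"
    ))
  }
  invisible(x)
}

#' @export
tidy.demographic_breakdown <- function(x, ...) {
  x$breakdown
}

#' @export
glance.demographic_breakdown <- function(x, ...) {
  tibble::tibble(
    n_quit_users = sum(x$breakdown$n_quit_users),
    n_inferred = sum(x$breakdown$n_inferred),
    inferable_pct = proportion_pct(
      sum(x$breakdown$n_inferred),
      max(sum(x$breakdown$n_quit_users), 1)
    ),
    age_split = x$age_split,
    any_significant = any(x$tests$significant)
  )
}
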