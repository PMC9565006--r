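period_axis_labels <- c(
  pre_announcement = "Before\nannouncement",
  between = "Announcement to\nimplementation",
  post_implementation = "After\nimplementation"
)

#' Plot per-period quit-mention proportions
#'
#' Bar chart of the percentage of tweets and of unique users mentioning
#' quitting vaping in each policy period.
#'
#' @param counts Per-period counts from [tabulate_periods()] or a tidied
#'   analysis.
#' @return A ggplot object.
#' @export
plot_quit_trend <- function(counts) {
  if (!"tweet_pct" %in% names(counts)) {
    counts <- counts |>
      dplyr::mutate(
        tweet_pct = proportion_pct(.data$n_quit_tweets, pmax(.data$n_tweets, 1)),
        user_pct = proportion_pct(.data$n_quit_users, pmax(.data$n_users, 1))
      )
  }
  long <- counts |>
    dplyr::select("period", "tweet_pct", "user_pct") |>
    tidyr::pivot_longer(
      c("tweet_pct", "user_pct"),
      names_to = "unit", values_to = "pct"
    ) |>
    dplyr::mutate(
      unit = dplyr::recode(.data$unit,
        tweet_pct = "Tweets", user_pct = "Unique users"
      ),
      period = factor(.data$period, levels = period_levels())
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$period, y = .data$pct, fill = .data$unit
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_discrete(labels = period_axis_labels) +
    ggplot2::labs(
      x = NULL, y = "Mentioning quitting vaping (%)", fill = NULL,
      title = "Quit-vaping mentions by policy period"
    ) +
    ggplot2::theme_minimal()
}

#' Plot demographic composition of quit mentioners
#'
#' Bar chart of the female and young-adult shares among inferable quit
#' mentioners, per policy period.
#'
#' @param breakdown A `demographic_breakdown` object or its `breakdown`
#'   tibble.
#' @return A ggplot object.
#' @export
plot_demographics <- function(breakdown) {
  if (inherits(breakdown, "demographic_breakdown")) {
    breakdown <- breakdown$breakdown
  }
  long <- breakdown |>
    dplyr::select("period", "female_pct", "young_pct") |>
    tidyr::pivot_longer(
      c("female_pct", "young_pct"),
      names_to = "measure", values_to = "pct"
    ) |>
    dplyr::mutate(
      measure = dplyr::recode(.data$measure,
        female_pct = "Female", young_pct = "Age 18-34"
      ),
      period = factor(.data$period, levels = period_levels())
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$period, y = .data$pct, fill = .data$measure
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_discrete(labels = period_axis_labels) +
    ggplot2::labs(
      x = NULL, y = "Share of inferable quit mentioners (%)", fill = NULL,
      title = "Demographics of quit-vaping mentioners"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vape_analysis <- function(object, ...) {
  plot_quit_trend(object$counts)
}

#' @export
autoplot.demographic_breakdown <- function(object, ...) {
  plot_demographics(object)
}
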