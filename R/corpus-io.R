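#' Read a tweet corpus from line-delimited JSON
#'
#' Parses a minimal 6-field JSONL tweet dialect: one JSON object per line
#' with required fields `tweet_id`, `user_id`, `created_at`, `text` and
#' optional `country_code` (ISO-3166 alpha-2) and `has_profile_face`.
#' Timestamps may be ISO-8601 (`2020-01-15T00:00:00Z`) or classic Twitter
#' style (`Wed Jan 15 00:00:00 +0000 2020`); both are canonicalised to UTC.
#'
#' Malformed lines (bad JSON, missing required field, unparseable timestamp)
#' are skipped with a warning reporting how many. Duplicate `tweet_id`s keep
#' the first occurrence, again with a warning. If more than half of the
#' non-empty lines are malformed the file is assumed to be the wrong format
#' and reading aborts.
#'
#' @param path Path to a JSONL file.
#' @return A tibble with columns `tweet_id`, `user_id`, `created_at`
#'   (POSIXct, UTC), `text`, `country_code`, `has_profile_face`.
#' @seealso [write_tweets_jsonl()]
#' @export
read_tweets_jsonl <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Cannot read tweet corpus: no such file '", path, "'"))
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) {
    return(empty_tweets())
  }
  parsed <- lapply(lines, function(l) {
    obj <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(obj) || !is.list(obj)) {
      return(NULL)
    }
    need <- c("tweet_id", "user_id", "created_at", "text")
    if (!all(need %in% names(obj))) {
      return(NULL)
    }
    ts <- parse_tweet_time(as.character(obj$created_at))
    if (is.na(ts)) {
      return(NULL)
    }
    tibble::tibble(
      tweet_id = as.character(obj$tweet_id),
      user_id = as.character(obj$user_id),
      created_at = ts,
      text = as.character(obj$text),
      country_code = as.character(obj$country_code %||% NA_character_),
      has_profile_face = as.logical(obj$has_profile_face %||% NA)
    )
  })
  bad <- sum(vapply(parsed, is.null, logical(1)))
  if (bad > length(lines) / 2) {
    rlang::abort(sprintf(
      "%d of %d lines in '%s' are malformed; this does not look like a tweet corpus.",
      bad, length(lines), path
    ))
  }
  if (bad > 0) {
    rlang::warn(sprintf("Skipped %d malformed line(s) in '%s'.", bad, path))
  }
  out <- dplyr::bind_rows(parsed)
  if (nrow(out) == 0) {
    return(empty_tweets())
  }
  dup <- duplicated(out$tweet_id)
  if (any(dup)) {
    rlang::warn(sprintf(
      "Dropped %d tweet(s) with duplicated tweet_id (first occurrence kept).",
      sum(dup)
    ))
    out <- out[!dup, ]
  }
  out
}

empty_tweets <- function() {
  tibble::tibble(
    tweet_id = character(), user_id = character(),
    created_at = as.POSIXct(character(), tz = "UTC"),
    text = character(), country_code = character(),
    has_profile_face = logical()
  )
}

# Accepts ISO-8601 (Z or +hh:mm / +hhmm offsets, optional 'T') and the
# classic Twitter "Day Mon DD HH:MM:SS +0000 YYYY" dialect. Scalar in,
# POSIXct (UTC) or NA out.
parse_tweet_time <- function(x) {
  na <- as.POSIXct(NA_character_, tz = "UTC")
  if (length(x) != 1 || is.na(x) || !nzchar(x)) {
    return(na)
  }
  if (grepl("^\\d{4}-\\d{2}-\\d{2}", x)) {
    y <- sub("Z$", "+0000", x)
    y <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", y)
    y <- sub("T", " ", y, fixed = TRUE)
    fmt <- if (grepl("[+-]\\d{4}$", y)) "%Y-%m-%d %H:%M:%S%z" else "%Y-%m-%d %H:%M:%S"
    out <- as.POSIXct(y, format = fmt, tz = "UTC")
    return(if (is.na(out)) na else out)
  }
  out <- withr::with_locale(c(LC_TIME = "C"), {
    as.POSIXct(x, format = "%a %b %d %H:%M:%S %z %Y", tz = "UTC")
  })
  if (is.na(out)) na else out
}

#' Write a tweet corpus as line-delimited JSON
#'
#' Inverse of [read_tweets_jsonl()]; timestamps are written as ISO-8601 UTC
#' and absent optional fields are omitted from the line, so write-then-read
#' is the identity on valid corpora.
#'
#' @param tweets Tweet tibble as returned by [read_tweets_jsonl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tweets_jsonl <- function(tweets, path) {
  lines <- vapply(seq_len(nrow(tweets)), function(i) {
    obj <- list(
      tweet_id = tweets$tweet_id[i],
      user_id = tweets$user_id[i],
      created_at = format(tweets$created_at[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      text = tweets$text[i]
    )
    if (!is.na(tweets$country_code[i])) {
      obj$country_code <- tweets$country_code[i]
    }
    if (!is.na(tweets$has_profile_face[i])) {
      obj$has_profile_face <- tweets$has_profile_face[i]
    }
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read an inferred-demographics table
#'
#' Reads the per-user demographics CSV standing in for facial-recognition
#' output: `user_id`, `age` (years), `gender` (`female`/`male`) and
#' `face_valid` (TRUE when exactly one face was detected, so age/gender are
#' usable). Rows with `face_valid = FALSE` are retained but flagged;
#' duplicated `user_id`s keep the first row with a warning.
#'
#' @param path Path to a CSV file with those four columns.
#' @return A tibble with one row per user.
#' @export
read_demographics <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such demographics file: '", path, "'"))
  }
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("user_id", "age", "gender", "face_valid")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "Demographics table is missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  tab <- tibble::tibble(
    user_id = as.character(tab$user_id),
    age = as.integer(tab$age),
    gender = as.character(tab$gender),
    face_valid = as.logical(tab$face_valid)
  )
  if (any(tab$age < 0, na.rm = TRUE)) {
    rlang::abort("Demographics table contains negative ages.")
  }
  dup <- duplicated(tab$user_id)
  if (any(dup)) {
    rlang::warn(sprintf(
      "Dropped %d duplicated user_id row(s) in demographics table (first kept).",
      sum(dup)
    ))
    tab <- tab[!dup, ]
  }
  tab
}

#' Write / read per-period count tables
#'
#' Round-tripping CSV serialisation for the per-period counts produced by
#' [tabulate_periods()]; rows are written in window order
#' (pre_announcement, between, post_implementation).
#'
#' @param counts Per-period counts tibble.
#' @param path Output path.
#' @return `path` invisibly (`write_counts_csv`); a counts tibble
#'   (`read_counts_csv`).
#' @export
write_counts_csv <- function(counts, path) {
  if (nrow(counts) == 0) {
    rlang::abort("`counts` must be non-empty.")
  }
  counts <- counts[order(match(counts$period, period_levels())), ]
  readr::write_csv(counts, path)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  tibble::as_tibble(tab)
}
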