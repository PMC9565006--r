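test_that("JSONL write then read is the identity on valid corpora", {
  tweets <- make_tweets(
    c("i quit vaping", "new juul pod", "vape tricks"),
    created_at = c(
      "2019-06-20T08:30:00Z", "2020-01-15T00:00:00Z", "2020-03-01T23:59:59Z"
    ),
    country_code = c("US", "GB", NA)
  )
  tweets$has_profile_face <- c(TRUE, NA, FALSE)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tweets_jsonl(tweets, path)
  back <- read_tweets_jsonl(path)
  expect_equal(as.data.frame(back), as.data.frame(tweets))
})

test_that("empty corpus file reads as an empty tibble without warnings", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), path)
  expect_no_warning(out <- read_tweets_jsonl(path))
  expect_equal(nrow(out), 0)
  expect_named(
    out,
    c("tweet_id", "user_id", "created_at", "text", "country_code",
      "has_profile_face")
  )
})

test_that("a single well-formed line round-trips its fields", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0(
    '{"tweet_id":"1","user_id":"u1",',
    '"created_at":"2020-01-15T00:00:00Z",',
    '"text":"i quit vaping","country_code":"US"}'
  ), path)
  out <- read_tweets_jsonl(path)
  expect_equal(out$tweet_id, "1")
  expect_equal(out$user_id, "u1")
  expect_equal(out$text, "i quit vaping")
  expect_equal(out$country_code, "US")
  expect_equal(out$created_at, as.POSIXct("2020-01-15", tz = "UTC"))
})

test_that("malformed lines are counted and skipped; too many is fatal", {
  good <- vapply(1:10, function(i) {
    sprintf(
      '{"tweet_id":"t%d","user_id":"u%d","created_at":"2020-01-15T00:00:00Z","text":"vape"}',
      i, i
    )
  }, character(1))
  bad <- c("{not json", '{"tweet_id":"x","text":"missing fields"}')
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(sample(c(good, bad)), path)
  expect_warning(out <- read_tweets_jsonl(path), "2 malformed")
  expect_equal(nrow(out), 10)

  path2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(good[1], bad, "also broken"), path2)
  expect_error(read_tweets_jsonl(path2), "malformed")
  expect_error(read_tweets_jsonl(tempfile()), "no such file")
})

test_that("ISO-8601 and classic Twitter timestamps parse to the same UTC instant", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"tweet_id":"a","user_id":"u","created_at":"2020-01-15T13:45:00Z","text":"vape"}',
    '{"tweet_id":"b","user_id":"u","created_at":"Wed Jan 15 13:45:00 +0000 2020","text":"vape"}',
    '{"tweet_id":"c","user_id":"u","created_at":"2020-01-15T08:45:00-05:00","text":"vape"}'
  ), path)
  out <- read_tweets_jsonl(path)
  expect_equal(length(unique(out$created_at)), 1)
  expect_equal(
    out$created_at[1],
    as.POSIXct("2020-01-15 13:45:00", tz = "UTC")
  )
})

test_that("duplicated tweet ids keep the first occurrence with a warning", {
  tweets <- make_tweets(c("vape one", "vape two"), tweet_id = c("t1", "t1"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tweets_jsonl(tweets, path)
  expect_warning(out <- read_tweets_jsonl(path), "duplicated tweet_id")
  expect_equal(out$text, "vape one")
})

test_that("demographics reader validates columns and flags unusable rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    user_id = sprintf("u%d", 1:5),
    age = c(27L, 40L, 19L, 55L, 33L),
    gender = c("female", "male", "female", "male", "female"),
    face_valid = c(TRUE, TRUE, FALSE, TRUE, FALSE)
  ), path)
  out <- read_demographics(path)
  expect_equal(nrow(out), 5)
  expect_equal(sum(out$face_valid), 3)

  # header-only file
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("user_id,age,gender,face_valid", path2)
  expect_equal(nrow(read_demographics(path2)), 0)

  # missing column is named in the error
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(user_id = "u1", age = 20L, gender = "male"), path3)
  expect_error(read_demographics(path3), "face_valid")

  # duplicated user keeps first row
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    user_id = c("u1", "u1"), age = c(20L, 30L),
    gender = c("male", "female"), face_valid = TRUE
  ), path4)
  expect_warning(out4 <- read_demographics(path4), "duplicated")
  expect_equal(out4$age, 20L)
})

test_that("counts CSV round-trips in window order", {
  counts <- tibble::tibble(
    period = c("post_implementation", "pre_announcement", "between"),
    n_tweets = c(30L, 10L, 20L),
    n_quit_tweets = c(3L, 1L, 2L),
    n_users = c(15L, 5L, 10L),
    n_quit_users = c(3L, 1L, 2L)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts_csv(counts, path)
  back <- read_counts_csv(path)
  expect_equal(
    back$period, c("pre_announcement", "between", "post_implementation")
  )
  expect_equal(
    dplyr::arrange(back, period),
    dplyr::arrange(counts, period)
  )
  expect_error(write_counts_csv(counts[0, ], path), "non-empty")
})
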