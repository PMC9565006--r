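test_that("percentages use half-up rounding to two decimals", {
  expect_equal(proportion_pct(1644, 691979), 0.24)
  expect_equal(proportion_pct(16, 39), 41.03)
  expect_equal(proportion_pct(0, 100), 0)
  # exact half rounds up (banker's rounding would give 0.12)
  expect_equal(proportion_pct(1, 800), 0.13)
  expect_equal(round_half_up(c(0.125, 0.135, -0.125), 2), c(0.13, 0.14, -0.13))
  expect_error(proportion_pct(1, 0), "positive")
  expect_error(proportion_pct(5, 4), "0 <= x <= n")
})

test_that("pooled z-test matches the closed form and handles degenerate input", {
  expect_warning(zt0 <- two_proportion_ztest(0, 10, 0, 20), "Pooled")
  expect_equal(zt0$z, 0)
  expect_equal(zt0$p_value, 1)

  zt <- two_proportion_ztest(5, 10, 5, 10)
  expect_equal(zt$z, 0)
  expect_equal(zt$p_value, 1)
  expect_false(zt$significant)

  zt1 <- two_proportion_ztest(189, 165782, 1644, 691979)
  expect_equal(zt1$z, 9.79, tolerance = 0.001)
  expect_lt(zt1$p_value, 0.001)
  expect_true(zt1$significant)

  zt2 <- two_proportion_ztest(7, 20, 16, 39)
  expect_equal(zt2$z, 0.45, tolerance = 0.02)
  expect_equal(zt2$p_value, 0.65, tolerance = 0.01)
  expect_false(zt2$significant)
})

test_that("z-test agrees with the chi-square oracle and is antisymmetric", {
  cases <- list(
    c(189, 165782, 345, 169375),
    c(185, 126735, 1624, 189686),
    c(7, 20, 16, 39),
    c(3, 17, 9, 41)
  )
  for (cs in cases) {
    zt <- two_proportion_ztest(cs[1], cs[2], cs[3], cs[4])
    # independent oracle: Pearson chi-square without continuity correction
    # equals z^2, with the identical p-value
    or <- suppressWarnings(
      prop.test(x = c(cs[1], cs[3]), n = c(cs[2], cs[4]), correct = FALSE)
    )
    expect_equal(zt$z^2, unname(or$statistic), tolerance = 1e-10)
    expect_equal(zt$p_value, or$p.value, tolerance = 1e-10)
    # p from z matches the closed normal form (absolute agreement)
    expect_lt(abs(zt$p_value - 2 * (1 - pnorm(abs(zt$z)))), 1e-12)
    # swapping groups negates z, keeps p
    sw <- two_proportion_ztest(cs[3], cs[4], cs[1], cs[2])
    expect_equal(sw$z, -zt$z, tolerance = 1e-12)
    expect_equal(sw$p_value, zt$p_value, tolerance = 1e-12)
  }
})

test_that("tidy and glance expose the test as tibbles", {
  zt <- two_proportion_ztest(5, 50, 20, 60, labels = c("pre", "post"))
  td <- tidy(zt)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$group1, "pre")
  expect_equal(td$estimate, 20 / 60 - 5 / 50)
  gl <- glance(zt)
  expect_named(gl, c("statistic", "p.value", "alpha", "significant"))
})

test_that("period tabulation counts tweets and unique users per period", {
  tweets <- tibble::tibble(
    user_id = c("a", "a", "a", "b", "b", "c", "d", "d", "e", "f"),
    period = c(
      "pre_announcement", "pre_announcement", "pre_announcement",
      "pre_announcement", "between", "between", "post_implementation",
      "post_implementation", "post_implementation", "excluded"
    ),
    is_quit = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  )
  counts <- tabulate_periods(tweets)
  expect_equal(counts$period, c("pre_announcement", "between", "post_implementation"))
  # user a posts 3 quit tweets in pre: 3 quit tweets, 1 quit user
  expect_equal(counts$n_tweets, c(4L, 2L, 3L))
  expect_equal(counts$n_quit_tweets, c(3L, 1L, 2L))
  expect_equal(counts$n_users, c(2L, 2L, 2L))
  expect_equal(counts$n_quit_users, c(1L, 1L, 2L))
  # excluded rows are ignored entirely
  expect_equal(sum(counts$n_tweets), 9L)

  # permutation invariance
  withr::with_seed(3, {
    shuffled <- tweets[sample(nrow(tweets)), ]
    expect_equal(tabulate_periods(shuffled), counts)
  })

  # empty period yields all-zero counts
  empty <- tabulate_periods(tweets[tweets$period == "between", ])
  expect_equal(
    unlist(empty[empty$period == "pre_announcement", -1]),
    c(n_tweets = 0L, n_quit_tweets = 0L, n_users = 0L, n_quit_users = 0L)
  )
})

test_that("first-mention-only crediting assigns repeat quitters to their first period", {
  tweets <- tibble::tibble(
    user_id = c("a", "a", "b"),
    period = c("pre_announcement", "post_implementation", "post_implementation"),
    is_quit = TRUE
  )
  both <- tabulate_periods(tweets)
  expect_equal(both$n_quit_users, c(1L, 0L, 2L))
  first <- tabulate_periods(tweets, first_mention_only = TRUE)
  expect_equal(first$n_quit_users, c(1L, 0L, 1L))
  # under first-mention crediting, per-period quit users sum to distinct quitters
  expect_equal(sum(first$n_quit_users), 2L)
})

test_that("pairwise period comparisons cover both units and all period pairs", {
  counts <- tibble::tibble(
    period = c("pre_announcement", "between", "post_implementation"),
    n_tweets = c(165782L, 169375L, 691979L),
    n_quit_tweets = c(189L, 345L, 1644L),
    n_users = c(126735L, 48368L, 189686L),
    n_quit_users = c(185L, 340L, 1624L)
  )
  cmp <- compare_periods(counts)
  expect_equal(nrow(cmp), 6)
  expect_setequal(unique(cmp$unit), c("tweets", "users"))
  pre_post <- cmp[cmp$unit == "tweets" &
    cmp$group1 == "pre_announcement" &
    cmp$group2 == "post_implementation", ]
  expect_equal(pre_post$pct1, 0.11)
  expect_equal(pre_post$pct2, 0.24)
  expect_lt(pre_post$p.value, 0.001)
})

test_that("demographic breakdown splits by gender and the [18, 35) age bin", {
  demographics <- tibble::tibble(
    user_id = sprintf("u%d", 1:8),
    age = c(27L, 34L, 35L, 44L, 19L, 17L, 50L, 29L),
    gender = c("female", "male", "female", "male", "female", "female", "male", "female"),
    face_valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  quit_users <- tibble::tibble(
    period = "pre_announcement",
    user_id = sprintf("u%d", 1:8)
  )
  bd <- demographic_breakdown(quit_users, demographics)
  row <- bd$breakdown[bd$breakdown$period == "pre_announcement", ]
  # u6 (<18) and u7 (face_valid FALSE) are unusable
  expect_equal(row$n_quit_users, 8L)
  expect_equal(row$n_inferred, 6L)
  # age 34 counts as young, 35 as old
  expect_equal(row$n_young, 4L)
  expect_equal(row$n_female, 4L)
  expect_equal(row$female_pct, proportion_pct(4, 6))
  # empty periods carry NA percentages
  empty <- bd$breakdown[bd$breakdown$period == "between", ]
  expect_equal(empty$n_inferred, 0L)
  expect_true(is.na(empty$female_pct))
})

test_that("demographic breakdown reproduces a hand-built two-period comparison", {
  demographics <- tibble::tibble(
    user_id = c(sprintf("p%d", 1:20), sprintf("q%d", 1:39)),
    age = c(rep(25L, 14), rep(45L, 6), rep(25L, 35), rep(45L, 4)),
    gender = c(
      rep("female", 7), rep("male", 13),
      rep("female", 16), rep("male", 23)
    ),
    face_valid = TRUE
  )
  quit_users <- tibble::tibble(
    period = rep(c("pre_announcement", "between"), c(20, 39)),
    user_id = c(sprintf("p%d", 1:20), sprintf("q%d", 1:39))
  )
  bd <- demographic_breakdown(quit_users, demographics)
  got <- bd$breakdown[match(c("pre_announcement", "between"), bd$breakdown$period), ]
  expect_equal(got$female_pct, c(35.00, 41.03))
  expect_equal(got$young_pct, c(70.00, 89.74))
  tests <- bd$tests
  expect_true(all(tests$p.value > 0.05))
})
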