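test_that("boxplot summaries handle constants and obvious outliers", {
  s <- boxplot_summary(c(5, 5, 5, 5))
  expect_equal(s$median, 5)
  expect_equal(s$q1, 5)
  expect_equal(s$q3, 5)
  expect_equal(s$whisker_low, 5)
  expect_equal(s$whisker_high, 5)
  expect_equal(s$outliers[[1]], numeric(0))

  s2 <- boxplot_summary(c(1, 2, 3, 4, 100))
  expect_equal(s2$outliers[[1]], 100)
  expect_equal(s2$whisker_high, 4)

  expect_error(boxplot_summary(c(NA_real_, NA_real_)), "non-missing")
})

test_that("boxplot summaries agree with the brute-force oracle", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(1:30, 1)
    v <- switch(sample(3, 1),
                round(runif(n, 0, 100)),          # integers with ties
                rnorm(n, 50, 20),                 # continuous
                sample(c(0, 0, 0, 100, runif(n)), n, replace = TRUE))
    s <- boxplot_summary(v)
    o <- oracle_boxplot(v)
    expect_equal(s$median, o$median, tolerance = 1e-12)
    expect_equal(s$q1, o$q1, tolerance = 1e-12)
    expect_equal(s$q3, o$q3, tolerance = 1e-12)
    expect_equal(s$whisker_low, o$whisker_low)
    expect_equal(s$whisker_high, o$whisker_high)
    expect_equal(s$outliers[[1]], o$outliers)
    expect_true(s$whisker_low <= s$q1 && s$q1 <= s$median &&
                  s$median <= s$q3 && s$q3 <= s$whisker_high)
  }
})

test_that("median ordering sorts within polarity groups with stable ties", {
  su <- tibble::tibble(item = c("a", "b", "c"),
                       polarity = "negative",
                       median = c(10, 30, 20))
  expect_equal(order_items_by_median(su), c("a", "c", "b"))
  expect_equal(order_items_by_median(su, direction = "desc"), c("b", "c", "a"))

  ties <- tibble::tibble(item = c("zz", "aa"), polarity = "positive",
                         median = c(5, 5))
  expect_equal(order_items_by_median(ties), c("aa", "zz"))

  d <- short_sim(seed = 31)
  s <- item_summaries(d)
  got <- order_items_by_median(s)
  q <- esm_questionnaire_of(d)
  for (pol in c("negative", "positive")) {
    codes <- got[got %in% q$code[q$polarity == pol]]
    med <- vapply(codes, function(cd) median(d[[cd]], na.rm = TRUE), numeric(1))
    expect_false(is.unsorted(med), info = pol)
  }
})

test_that("local regression reproduces linear data exactly", {
  set.seed(5)
  t <- as.POSIXct("2017-03-01", tz = "UTC") + cumsum(runif(40, 2, 30)) * 3600
  y <- 3 + 0.5 * as.numeric(t) / 86400
  for (bw in c(0.15, 0.4, 1)) {
    sm <- loess_smooth(t, y, bandwidth = bw)
    expect_lt(max(abs(sm$fitted - y)), 1e-9)
  }
})

test_that("local regression matches the pointwise weighted-LS oracle", {
  set.seed(17)
  t <- as.POSIXct("2017-03-01", tz = "UTC") + sort(runif(60, 0, 40)) * 86400
  y <- 50 + 20 * sin(seq(0, 6, length.out = 60)) + rnorm(60, 0, 4)
  y[c(7, 23)] <- NA
  grid <- t[seq(1, 60, by = 3)]
  for (bw in c(0.2, 0.5, 1)) {
    sm <- loess_smooth(t, y, bandwidth = bw, grid_times = grid)
    o <- oracle_loess(t, y, bandwidth = bw, grid_times = grid)
    expect_lt(max(abs(sm$fitted - o) / pmax(abs(o), 1)), 1e-9)
  }
})

test_that("smoothing is shift and scale equivariant", {
  set.seed(3)
  t <- as.POSIXct("2017-03-01", tz = "UTC") + sort(runif(50, 0, 30)) * 86400
  y <- runif(50, 0, 100)
  base <- loess_smooth(t, y, bandwidth = 0.3)
  tr <- loess_smooth(t, 2.5 * y + 7, bandwidth = 0.3)
  expect_lt(max(abs(tr$fitted - (2.5 * base$fitted + 7))), 1e-8)
})

test_that("local regression guards its preconditions", {
  t <- as.POSIXct("2017-03-01", tz = "UTC") + (1:2) * 3600
  expect_error(loess_smooth(t, c(1, 2)), "at least 3")
  expect_error(loess_smooth(t, c(1, 2), bandwidth = 0), "bandwidth")
  t3 <- as.POSIXct("2017-03-01", tz = "UTC") + (1:3) * 3600
  expect_equal(attr(loess_smooth(t3, c(1, 2, 3)), "bandwidth"), 0.2)
  # all observations at one instant: falls back to the plain mean
  t0 <- rep(as.POSIXct("2017-03-01 09:00", tz = "UTC"), 4)
  sm <- loess_smooth(t0, c(1, 2, 3, 4), grid_times = t0[1])
  expect_equal(sm$fitted, 2.5)
})

test_that("polarity composites average what is available", {
  q <- mini_questionnaire()
  rec <- mini_records()
  rec$NegA[1] <- 10; rec$NegB[1] <- 20
  rec$NegA[2] <- 10; rec$NegB[2] <- NA
  d <- esm_dataset(rec, q)
  comp <- composite_series(d, "negative")
  expect_equal(comp$value[1], 15)
  expect_equal(comp$value[2], 10)
  expect_error(composite_series(d, "purple"))

  # unanswered prompts propagate as missing
  rec2 <- mini_records()[-2, ]
  d2 <- esm_dataset(rec2, q, study_start = as.Date("2017-03-01"),
                    study_end = as.Date("2017-03-02"))
  expect_true(is.na(composite_series(d2, "negative")$value[2]))
})

test_that("noise-free composites equal the group mean of the configured means", {
  cfg <- simulation_config(study_end = as.Date("2017-03-10"), sigma = 0, phi = 0,
                           episodes = episode_spec("2017-05-01", "2017-05-02")[0, ],
                           compliance_prob = 1,
                           block_missing = tibble::tibble(start_date = as.Date(character()),
                                                          end_date = as.Date(character())),
                           seed = 2)
  d <- simulate_esm(cfg)
  q <- esm_questionnaire_of(d)
  neg <- q$code[q$polarity == "negative" & q$response_kind == "slider_0_100"]
  expected <- mean(round(cfg$mu[neg]))
  comp <- composite_series(d, "negative")
  expect_true(all(abs(comp$value - expected) < 1e-9))
})

test_that("episode flagging finds planted setbacks and nothing in flat data", {
  flat <- simulate_esm(simulation_config(
    study_end = as.Date("2017-08-31"), sigma = 0, phi = 0,
    episodes = episode_spec("2017-05-01", "2017-05-02")[0, ],
    compliance_prob = 1,
    block_missing = tibble::tibble(start_date = as.Date(character()),
                                   end_date = as.Date(character())),
    seed = 3))
  expect_equal(nrow(flag_episodes(flat)), 0)

  one <- simulate_esm(simulation_config(
    study_end = as.Date("2018-02-27"), sigma = 10,
    episodes = episode_spec("2017-07-01", "2017-07-31", negative_shift = 30,
                            positive_shift = 10, ramp_days = 3),
    seed = 12))
  w1 <- flag_episodes(one)
  expect_equal(nrow(w1), 1)
  expect_true(w1$start <= as.Date("2017-07-31") && w1$end >= as.Date("2017-07-01"))

  two <- simulate_esm(simulation_config(seed = 13,
    episodes = dplyr::bind_rows(
      episode_spec("2017-04-10", "2017-05-12", negative_shift = 45),
      episode_spec("2017-09-20", "2017-12-24", negative_shift = 45))))
  w2 <- flag_episodes(two)
  expect_equal(nrow(w2), 2)
  expect_true(all(diff(as.numeric(w2$start)) > 0))
  expect_true(w2$start[1] <= as.Date("2017-05-12") && w2$end[1] >= as.Date("2017-04-10"))
  expect_true(w2$start[2] <= as.Date("2017-12-24") && w2$end[2] >= as.Date("2017-09-20"))
})

test_that("missingness accounting is complete and conserved", {
  full <- esm_dataset(mini_records(), mini_questionnaire())
  m0 <- missingness_summary(full)
  expect_equal(nrow(m0$gaps), 0)
  expect_equal(m0$items$fraction[m0$items$item == "NegA"], 0)

  # with perfect compliance elsewhere, the mid-May block is one 42-prompt gap
  clean <- simulate_esm(simulation_config(seed = 8, compliance_prob = 1,
                                          study_end = as.Date("2017-06-30")))
  mc <- missingness_summary(clean)
  expect_equal(mc$gaps$n_prompts, 42L)
  expect_equal(as.Date(mc$gaps$start, tz = "UTC"), as.Date("2017-05-13"))

  d <- simulate_esm(simulation_config(seed = 8, study_end = as.Date("2017-06-30")))
  m <- missingness_summary(d)
  # the block window sits inside one maximal gap of at least 42 prompts
  blk <- m$gaps[m$gaps$start <= as.POSIXct("2017-05-13", tz = "UTC") + 86400 &
                  m$gaps$end >= as.POSIXct("2017-05-26", tz = "UTC"), ]
  expect_equal(nrow(blk), 1)
  expect_gte(blk$n_prompts, 42L)
  expect_true(all(m$items$n_missing + m$items$n_observed == nrow(d)))
  expect_true(all(m$items$fraction >= 0 & m$items$fraction <= 1))
  # gaps are sorted and non-overlapping
  if (nrow(m$gaps) > 1) {
    expect_true(all(diff(as.numeric(m$gaps$start)) > 0))
    expect_true(all(utils::head(m$gaps$end, -1) < utils::tail(m$gaps$start, -1)))
  }
  expect_equal(glance(m)$n_prompts, nrow(d))
})

test_that("tidiers expose fitted objects as tibbles", {
  d <- short_sim(seed = 21)
  sm <- loess_smooth(d$time[d$answered], d$Sad[d$answered], item = "Sad")
  expect_equal(glance(sm)$bandwidth, 0.2)
  expect_equal(nrow(tidy(sm)), sum(d$answered))
  s <- item_summaries(d)
  td <- tidy(s)
  expect_true(all(c("item", "polarity", "median", "n_outliers") %in% names(td)))
  ep <- flag_episodes(d)
  expect_true(is.numeric(glance(ep)$threshold))
})
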