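test_that("circle specs encode scores as fill fractions with polarity arcs", {
  d <- mini_dataset()
  rec <- d[1, ]
  rec$NegA <- 100; rec$NegB <- 0; rec$PosA <- 50
  spec <- build_circle_spec(rec, mini_questionnaire())
  nodes <- spec$nodes
  expect_equal(nodes$fill_fraction[nodes$item == "NegA"], 1.0)
  expect_equal(nodes$fill_fraction[nodes$item == "NegB"], 0.0)
  expect_equal(nodes$fill_fraction[nodes$item == "PosA"], 0.5)
  # negative items on the left half (180..360 clockwise from 12), positive right
  expect_true(all(nodes$angle[nodes$item %in% c("NegA", "NegB")] > 180))
  expect_true(all(nodes$angle[nodes$item == "PosA"] < 180))
  # deterministic resolution
  expect_identical(spec, build_circle_spec(rec, mini_questionnaire()))
})

test_that("every questionnaire item maps to exactly one node or badge", {
  d <- short_sim(seed = 14)
  q <- esm_questionnaire_of(d)
  spec <- build_circle_spec(d[d$answered, ][1, ], q)
  expect_setequal(spec$nodes$item, ring_codes_for_test(q))
  expect_setequal(
    spec$badges$kind,
    c("sleep", "company", "cancelled_appointment", "contact_count",
      "pleasant_event", "unpleasant_event", "comment"))
  # nodes + items folded into badges = whole questionnaire
  badge_items <- c("Slept", "Sleep", "Comp", "Canc", "Cont", "Event", "Pleas", "Unpl")
  expect_setequal(c(spec$nodes$item, badge_items), q$code)
  # evenly spaced within each arc
  neg <- sort(spec$nodes$angle[spec$nodes$angle > 180])
  expect_equal(length(unique(round(diff(neg), 9))), 1)
})

test_that("badges reflect the recorded context and conditional answers", {
  d <- mini_dataset()
  rec <- d[1, ]
  rec$Slp <- "yes"; rec$SlpQ <- 80; rec$Comp <- "no"; rec$Cnt <- 3
  # outside the packaged questionnaire, badge kinds fall back to item codes
  spec <- build_circle_spec(rec, mini_questionnaire())
  b <- spec$badges
  expect_true(b$present[b$kind == "Slp"])
  expect_equal(b$intensity[b$kind == "Slp"], 0.8)
  expect_false(b$present[b$kind == "company"])  # canonical code, canonical kind
  expect_equal(b$glyph[b$kind == "Cnt"], "3")

  rec$Slp <- "no"; rec$SlpQ <- NA
  b2 <- build_circle_spec(rec, mini_questionnaire())$badges
  expect_false(b2$present[b2$kind == "Slp"])
  expect_true(is.na(b2$intensity[b2$kind == "Slp"]))
})

test_that("rendering identical specs is byte-identical and size-independent", {
  d <- short_sim(seed = 6)
  spec <- build_circle_spec(d[d$answered, ][1, ])
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_circle(spec, f1); render_circle(spec, f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
  # geometry lives in the spec, not the device: respecifying at another
  # size changes nothing about angles or fills
  f3 <- withr::local_tempfile(fileext = ".png")
  render_circle(spec, f3, size = 200)
  spec2 <- build_circle_spec(d[d$answered, ][1, ])
  expect_identical(spec$nodes, spec2$nodes)

  # unanswered prompts render a distinct placeholder, not an all-grey glyph
  un <- d[!d$answered, ][1, ]
  spec_un <- build_circle_spec(un)
  expect_false(spec_un$answered)
  f4 <- withr::local_tempfile(fileext = ".png")
  render_circle(spec_un, f4, size = 200)
  expect_false(identical(readBin(f3, "raw", 1e7), readBin(f4, "raw", 1e7)))
})

test_that("week grids are 3 x 7 with blanks outside the study window", {
  d <- short_sim(seed = 6)  # study starts Wed 2017-03-01
  g <- build_week_grid(d, as.Date("2017-03-06"))
  expect_equal(nrow(g), 21)
  expect_equal(levels(g$weekday)[1], format(as.Date("2017-03-06"), "%a"))
  expect_true(all(!purrr::map_lgl(g$spec, is.null)))

  first <- build_week_grid(d, as.Date("2017-03-01"))
  expect_equal(nrow(first), 21)
  # Mon/Tue before the study started are blank in all three slots
  blanks <- purrr::map_lgl(first$spec, is.null)
  expect_equal(sum(blanks), 6)
  expect_true(all(first$date[blanks] < as.Date("2017-03-01")))

  n_answered <- sum(purrr::map_lgl(g$spec, ~ !is.null(.x) && .x$answered))
  n_placeholder <- sum(purrr::map_lgl(g$spec, ~ !is.null(.x) && !.x$answered))
  expect_equal(n_answered + n_placeholder, 21)
  expect_equal(n_placeholder,
               sum(!d$answered[d$date >= as.Date("2017-03-06") &
                                 d$date <= as.Date("2017-03-12")]))
})

test_that("legend covers every node, both colours, and the grey caveat", {
  q <- default_questionnaire()
  spec <- legend_spec(q)
  expect_setequal(spec$code[spec$entry == "node"], ring_codes_for_test(q))
  expect_setequal(spec$code[spec$entry == "colour"], c("positive", "negative"))
  expect_match(spec$text[spec$entry == "note"], "not filled in")
  f <- withr::local_tempfile(fileext = ".png")
  render_legend(q, f)
  expect_gt(file.info(f)$size, 0)
})

test_that("the timeline builds two polarity panels and guards sparse data", {
  d <- short_sim(seed = 6)
  p <- plot_timeline(d, highlight = as.Date(c("2017-03-06", "2017-03-12")),
                     show_raw = TRUE)
  expect_s3_class(p, "ggplot")
  expect_error(plot_timeline(d, highlight = as.Date(c("2019-01-01", "2019-01-07"))),
               "outside")
  few <- esm_dataset(mini_records()[1:2, ], mini_questionnaire(),
                     study_start = as.Date("2017-03-01"),
                     study_end = as.Date("2017-03-02"))
  expect_error(plot_timeline(few), "3 answered")
})

test_that("boxplot panel shows only always-asked mood sliders, ordered on median", {
  d <- short_sim(seed = 6)
  s <- item_summaries(d)
  q <- esm_questionnaire_of(d)
  expect_true(all(s$item %in% q$code[q$response_kind == "slider_0_100"]))
  expect_false(any(c("Cont", "Comp", "Event", "Pleas", "Unpl", "Sleep") %in% s$item))
  p <- plot_boxplots(d)
  expect_s3_class(p, "ggplot")
})

test_that("poster pagination follows the week count", {
  d <- short_sim(seed = 6, end = "2017-04-04")  # 6 ISO weeks
  f <- withr::local_tempfile(fileext = ".pdf")
  res <- make_poster(d, f, weeks_per_page = 4)
  expect_equal(res$n_weeks, 6)
  expect_equal(res$n_pages, 2)
  expect_gt(file.info(f)$size, 0)
  res2 <- make_poster(d, f, weeks_per_page = 4, tint = TRUE)
  expect_equal(res2$n_pages, 2)
})
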