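test_that("packaged questionnaire matches the study protocol", {
  q <- default_questionnaire()
  expect_equal(nrow(q), 23)
  expect_false(anyDuplicated(q$code) > 0)
  expect_equal(sum(q$polarity == "negative"), 9)
  expect_equal(sum(q$polarity == "positive"), 9)
  expect_equal(sum(q$polarity == "neutral"), 2)
  expect_equal(sum(q$polarity == "event"), 3)
  # safe-contact count item is scored 0..4
  cont <- q[grepl("contact with someone you feel safe", q$label) &
              q$response_kind == "likert_count", ]
  expect_equal(nrow(cont), 1)
  expect_equal(cont$likert_max, 4L)
  # sleep quality only asked after sleeping
  sleep <- q[q$code == "Sleep", ]
  expect_equal(sleep$conditional_on, "Slept")
  expect_equal(sleep$conditional_value, "yes")
  # event intensities hang off the event gate
  expect_equal(q$conditional_on[q$code %in% c("Pleas", "Unpl")], c("Event", "Event"))
  # polarity override is honoured
  q2 <- default_questionnaire(polarity = c(Bed = "neutral"))
  expect_equal(q2$polarity[q2$code == "Bed"], "neutral")
})

test_that("questionnaire invariants are enforced at construction", {
  expect_error(
    esm_questionnaire(dplyr::bind_rows(
      esm_item("A", "a", "positive", "slider_0_100"),
      esm_item("A", "b", "negative", "slider_0_100"))),
    "duplicate")
  expect_error(
    esm_questionnaire(
      esm_item("Kid", "child", "positive", "slider_0_100",
               conditional_on = "Ghost", conditional_value = "yes")),
    "unknown item")
  expect_error(
    esm_questionnaire(dplyr::bind_rows(
      esm_item("Kid", "child", "positive", "slider_0_100",
               conditional_on = "Par", conditional_value = "yes"),
      esm_item("Par", "parent", "neutral", "yes_no"))),
    "earlier")
  expect_error(esm_item("X", "x", "positive", "likert_count"), "likert_max")
})

test_that("prompt schedule validates its timing constants", {
  s <- prompt_schedule()
  expect_equal(esmviz:::format_clock(s$daily_times), c("09:00", "15:00", "21:00"))
  expect_equal(s$instruction_window_min, 15)
  expect_equal(s$reminder_offset_min, 30)
  expect_equal(s$expiry_offset_min, 60)
  expect_error(prompt_schedule(daily_times = c("09:00", "09:00", "21:00")), "increasing")
  expect_error(prompt_schedule(reminder_offset_min = 90), "expiry")
  expect_error(prompt_schedule(instruction_window_min = 0), "instruction")
})

test_that("slot assignment picks the nearest beep, earlier on ties", {
  t <- as.POSIXct(c("2017-03-01 09:07", "2017-03-01 12:00", "2017-03-01 20:40"),
                  tz = "UTC")
  expect_equal(as.character(slot_of(t)), c("morning", "morning", "evening"))
  expect_error(slot_of(t[1], prompt_schedule(daily_times = c("09:00", "21:00"))),
               "3 daily")
})

test_that("slot boundaries sit at the midpoints between beeps", {
  s <- prompt_schedule()
  minutes <- seq(0, 1439, by = 7)
  t <- as.POSIXct("2017-03-01", tz = "UTC") + minutes * 60
  got <- as.integer(slot_of(t, s))
  want <- vapply(minutes, oracle_slot, integer(1), daily_times = s$daily_times)
  expect_equal(got, want)
  # every minute lands in exactly one slot
  expect_false(anyNA(slot_of(as.POSIXct("2017-03-01", tz = "UTC") + (0:1439) * 60, s)))
})

test_that("schema configs round-trip through YAML", {
  q <- default_questionnaire()
  s <- prompt_schedule()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_questionnaire(q, path, schedule = s)
  back <- read_questionnaire(path)
  expect_equal(tibble::as_tibble(back$questionnaire), tibble::as_tibble(q))
  expect_equal(back$schedule$daily_times, s$daily_times)
  expect_equal(back$schedule$expiry_offset_min, s$expiry_offset_min)
})

test_that("validation reports planted violations and nothing else", {
  q <- mini_questionnaire()
  rec <- mini_records()
  clean <- esm_dataset(rec, q)
  expect_equal(nrow(validate_dataset(clean)), 0)

  bad <- rec
  bad$NegA[2] <- 101                              # slider out of range
  bad$SlpQ[3] <- 50                               # sleep quality while Slp == "no"
  bad$Cnt[5] <- 9                                 # count above likert_max
  d <- esm_dataset(bad, q)
  f <- validate_dataset(d)
  expect_setequal(f$rule, c("value_out_of_range", "conditional_violation",
                            "likert_out_of_range"))
  expect_match(f$message[f$rule == "value_out_of_range"], "out of range \\[0,100\\]")
  expect_equal(f$item[f$rule == "conditional_violation"], "SlpQ")

  # idempotent and side-effect free
  expect_identical(f, validate_dataset(d))
})

test_that("empty datasets validate vacuously", {
  d <- esm_dataset(mini_records()[0, ], mini_questionnaire(),
                   study_start = as.Date("2017-03-01"),
                   study_end = as.Date("2017-03-02"))
  expect_equal(nrow(d), 6)          # prompts materialized, all unanswered
  expect_false(any(d$answered))
  expect_equal(nrow(validate_dataset(d)), 0)
})

test_that("duplicate prompt submissions keep the first and get flagged", {
  rec <- mini_records()
  dup <- rec[c(1, 1, 2:6), ]
  dup$NegA[2] <- 99  # the later duplicate, should be dropped
  d <- esm_dataset(dup, mini_questionnaire())
  expect_equal(nrow(d), 6)
  expect_equal(d$NegA[1], 10)
  f <- validate_dataset(d)
  expect_true("duplicate_prompt" %in% f$rule)
})

test_that("unknown item columns are a structural error", {
  rec <- mini_records()
  rec$Mystery <- 1
  expect_error(esm_dataset(rec, mini_questionnaire()), "Mystery")
})
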