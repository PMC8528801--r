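test_that("one frame per ISO week, overlay equal to the grid week", {
  d52 <- simulate_esm(simulation_config(seed = 1))   # 2017-03-01 .. 2018-02-27
  fr <- build_week_frames(d52)
  expect_equal(nrow(fr), 53)   # 52 weeks straddling partial boundary weeks
  expect_true(all(diff(as.numeric(fr$week_start)) == 7))
  expect_equal(as.numeric(fr$week_end - fr$week_start), rep(6, 53))

  one <- short_sim(seed = 2, end = "2017-03-07")
  expect_equal(nrow(build_week_frames(one)), 2)  # Wed start straddles two ISO weeks
  aligned <- esm_dataset(mini_records(), mini_questionnaire(),
                         study_start = as.Date("2017-03-06"),
                         study_end = as.Date("2017-03-12"))
  expect_equal(nrow(build_week_frames(aligned)), 1)
})

test_that("the GIF encoder writes valid animations with conserved frame counts", {
  mk <- function(shade) array(shade, dim = c(20, 30, 3))
  frames <- list(mk(0.2), mk(0.5), mk(0.9))
  f <- withr::local_tempfile(fileext = ".gif")
  res <- write_gif(frames, f, fps = 1)
  expect_equal(res$n_frames, 3)
  expect_equal(rawToChar(readBin(f, "raw", 6)), "GIF89a")
  expect_equal(gif_frame_count(f), 3)

  # frame delay stores 1 fps as 100 centiseconds
  bytes <- readBin(f, "raw", file.info(f)$size)
  gce <- which(bytes == as.raw(0x21))[
    which(bytes[which(bytes == as.raw(0x21)) + 1] == as.raw(0xF9))[1]]
  delay <- as.integer(bytes[gce + 4]) + 256L * as.integer(bytes[gce + 5])
  expect_equal(delay, 100)

  # re-encoding the same frames conserves the count
  write_gif(frames, f, fps = 2)
  expect_equal(gif_frame_count(f), 3)

  expect_error(write_gif(list(mk(0.1), array(0.1, dim = c(10, 30, 3))), f),
               "identical dimensions")
  expect_error(encode_video(character(), f), "at least one")
})

test_that("requesting an MP4 names the GIF fallback", {
  expect_error(encode_video("frame_001.png", "out.mp4"), "GIF fallback|\\.gif")
})

test_that("the movie pipeline yields one encoded frame per study week", {
  d <- esm_dataset(mini_records(), mini_questionnaire(),
                   study_start = as.Date("2017-02-27"),
                   study_end = as.Date("2017-03-26"))   # 4 aligned ISO weeks
  f <- withr::local_tempfile(fileext = ".gif")
  res <- esm_movie(d, f, width = 500, height = 400)
  expect_equal(res$n_frames, 4)
  expect_equal(gif_frame_count(f), 4)
})

test_that("the report is self-contained with curves equal to the stats output", {
  d <- short_sim(seed = 23, end = "2017-03-21")
  f <- withr::local_tempfile(fileext = ".html")
  build_report(d, report_toggles(), f)
  html <- paste(readLines(f, warn = FALSE), collapse = "\n")
  expect_false(grepl("src=\"http", html))
  expect_false(grepl("<link", html))

  json <- sub('.*<script id="esm-data" type="application/json">', "", html)
  json <- sub("</script>.*", "", json)
  payload <- jsonlite::fromJSON(json)
  expect_equal(payload$bandwidth, 0.2)
  curves <- smooth_items(d, bandwidth = 0.2)
  for (code in c("Sad", "Enco")) {
    expect_equal(payload$items[[code]]$fitted,
                 curves$fitted[curves$item == code], tolerance = 1e-6)
  }
  # every visible item has a polyline and a checkbox
  expect_equal(stringr::str_count(html, 'class="curve curve-'),
               length(unique(curves$item)))
  expect_equal(stringr::str_count(html, 'class="item-toggle"'),
               length(unique(curves$item)))
  # a week grid image per study week, embedded inline
  expect_equal(stringr::str_count(html, "data:image/png;base64"),
               nrow(build_week_frames(d)))
})

test_that("report toggles control comments, item subset, raw overlay and zoom", {
  d <- short_sim(seed = 23, end = "2017-03-21")
  # plant a recognizable comment
  idx <- which(d$answered)[1]
  d$comment[idx] <- "travel tomorrow, very anxious"

  f1 <- withr::local_tempfile(fileext = ".html")
  build_report(d, report_toggles(show_comments = FALSE), f1)
  h1 <- paste(readLines(f1, warn = FALSE), collapse = "\n")
  expect_false(grepl("travel tomorrow, very anxious", h1))

  f2 <- withr::local_tempfile(fileext = ".html")
  build_report(d, report_toggles(visible_items = "Sad",
                                 zoom = as.Date(c("2017-03-06", "2017-03-12")),
                                 show_raw_overlay = TRUE), f2)
  h2 <- paste(readLines(f2, warn = FALSE), collapse = "\n")
  expect_equal(stringr::str_count(h2, 'class="curve curve-'), 1)
  expect_true(grepl("curve-Sad", h2))
  expect_true(grepl('id="zoom-start" value="2017-03-06"', h2))
  expect_true(grepl('id="toggle-raw" checked', h2))
  expect_true(grepl("travel tomorrow, very anxious", h2))
})
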