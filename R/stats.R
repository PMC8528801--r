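#' Five-number boxplot summary with Tukey fences
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7). Whiskers extend to the most extreme data
#' points within 1.5 times the interquartile range of the hinges; points
#' beyond the fences are returned as outliers.
#'
#' In degenerate samples where every data point beyond a hinge falls
#' outside its fence, the whisker on that side collapses to the hinge
#' itself (interpolated quartiles can exceed all non-outlying points);
#' otherwise whiskers are actual data points.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @param coef Whisker multiplier (1.5, the Tukey convention).
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, and `outliers` (a list column).
#' @export
#' @examples
#' boxplot_summary(c(1, 2, 3, 4, 100))
boxplot_summary <- function(values, coef = 1.5) {
  v <- values[!is.na(values)]
  if (!length(v)) rlang::abort("boxplot_summary: no non-missing values")
  qs <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - coef * iqr
  hi_fence <- qs[3] + coef * iqr
  inside <- v[v >= lo_fence & v <= hi_fence]
  tibble::tibble(
    n = length(v), median = qs[2], q1 = qs[1], q3 = qs[3],
    whisker_low = min(inside, qs[1]), whisker_high = max(inside, qs[3]),
    outliers = list(sort(v[v < lo_fence | v > hi_fence])))
}

#' Boxplot summaries for every displayable item
#'
#' Summarizes each unconditional positive/negative slider item of the
#' dataset. Event items and count items, which are not present at every
#' prompt, are excluded — as are yes/no context items, which have no
#' meaningful quartiles.
#'
#' @param data An `esm_df`.
#' @return A tibble of class `esm_boxstats`: one row per item with its
#'   polarity and [boxplot_summary()] columns.
#' @export
item_summaries <- function(data) {
  q <- esm_questionnaire_of(data)
  codes <- ring_codes(q)
  rows <- purrr::map(codes, function(code) {
    v <- data[[code]]
    if (all(is.na(v))) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(item = code, polarity = q$polarity[q$code == code]),
      boxplot_summary(v))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("esm_boxstats", class(tibble::tibble())))
}

#' Order items by median within polarity groups
#'
#' Reproduces the boxplot-panel ordering: within each polarity group,
#' items sorted by median (ascending by default), ties broken
#' alphabetically by item code. Groups are kept separate (negative then
#' positive).
#'
#' @param summaries An `esm_boxstats` tibble from [item_summaries()] (or
#'   any tibble with `item`, `polarity`, `median` columns).
#' @param direction `"asc"` or `"desc"`.
#' @return Character vector of item codes.
#' @export
order_items_by_median <- function(summaries, direction = c("asc", "desc")) {
  direction <- rlang::arg_match(direction)
  if (!nrow(summaries)) rlang::abort("no summaries to order")
  s <- dplyr::arrange(tibble::as_tibble(summaries), .data$item)
  s <- if (direction == "asc") {
    dplyr::arrange(s, .data$median, .data$item, .by_group = FALSE)
  } else {
    dplyr::arrange(s, dplyr::desc(.data$median), .data$item)
  }
  grp <- factor(s$polarity, levels = c("negative", "positive", "neutral", "event"))
  unlist(split(s$item, grp), use.names = FALSE)
}

#' Local regression smoothing of an ESM series
#'
#' Classical LOESS with a nearest-neighbour fraction bandwidth: at each
#' grid time a degree-1 weighted least squares line is fitted over the
#' `ceiling(bandwidth * n)` points nearest in time, with tricube weights
#' `(1 - (d / d_max)^3)^3`, and evaluated at the grid time. No robustness
#' iterations are performed. Time distance is measured in days, so two
#' prompts on the same day are 0.25 days apart under the default
#' three-beep schedule. The default bandwidth of 0.2 is deliberately low;
#' because smoothing can still conceal sudden jumps, vary the bandwidth
#' and overlay the raw data when interpreting the curves.
#'
#' @param times `POSIXct` (or numeric) observation times.
#' @param values Numeric values; `NA`s are dropped before fitting.
#' @param bandwidth Fraction of the data in each local window, in (0, 1].
#' @param grid_times Evaluation times; defaults to the observation times.
#' @param item Optional label stored on the result.
#' @return A tibble of class `esm_smooth` with columns `time`, `fitted`,
#'   and attributes `item`, `bandwidth`, `n`.
#' @export
loess_smooth <- function(times, values, bandwidth = 0.2, grid_times = times,
                         item = NA_character_) {
  if (bandwidth <= 0 || bandwidth > 1) rlang::abort("bandwidth must be in (0, 1]")
  keep <- !is.na(values) & !is.na(times)
  t0 <- as.numeric(as.POSIXct(times, tz = "UTC"))[keep] / 86400
  y <- values[keep]
  if (length(y) < 3) rlang::abort("loess_smooth: need at least 3 non-missing points")
  g <- as.numeric(as.POSIXct(grid_times, tz = "UTC")) / 86400
  n <- length(y)
  q <- max(2L, ceiling(bandwidth * n))
  fitted <- vapply(g, function(t) {
    d <- abs(t0 - t)
    dmax <- sort(d, partial = q)[q]
    if (dmax == 0) {
      # all nearest points at the grid time itself: plain mean
      return(mean(y[d == 0]))
    }
    w <- (1 - pmin(d / dmax, 1)^3)^3
    if (sum(w) == 0) w <- as.numeric(d <= dmax)
    sw <- sum(w)
    xm <- sum(w * t0) / sw
    ym <- sum(w * y) / sw
    sxx <- sum(w * (t0 - xm)^2)
    if (sxx < 1e-12) return(ym)  # zero time spread within the window
    beta <- sum(w * (t0 - xm) * (y - ym)) / sxx
    ym + beta * (t - xm)
  }, numeric(1))
  structure(
    tibble::tibble(time = grid_times, fitted = fitted),
    item = item, bandwidth = bandwidth, n = n,
    class = c("esm_smooth", class(tibble::tibble())))
}

#' Smoothed curves for a set of items
#'
#' @param data An `esm_df`.
#' @param items Item codes to smooth; defaults to all ring (unconditional
#'   positive/negative slider) items.
#' @param bandwidth Passed to [loess_smooth()].
#' @return A tibble with columns `item`, `polarity`, `time`, `fitted`.
#' @export
smooth_items <- function(data, items = NULL, bandwidth = 0.2) {
  q <- esm_questionnaire_of(data)
  items <- items %||% ring_codes(q)
  purrr::map_dfr(items, function(code) {
    ok <- data$answered & !is.na(data[[code]])
    if (sum(ok) < 3) return(NULL)
    sm <- loess_smooth(data$time[ok], data[[code]][ok], bandwidth = bandwidth,
                       grid_times = data$time[ok], item = code)
    tibble::tibble(item = code, polarity = q$polarity[q$code == code],
                   time = sm$time, fitted = sm$fitted)
  })
}

#' Per-prompt polarity composite
#'
#' For each prompt, the mean of the available slider items of the given
#' polarity; `NA` when none is available (e.g. unanswered prompts).
#'
#' @param data An `esm_df`.
#' @param polarity `"positive"` or `"negative"`.
#' @return A tibble `time`, `date`, `slot`, `value`.
#' @export
composite_series <- function(data, polarity = c("negative", "positive")) {
  polarity <- rlang::arg_match(polarity)
  q <- esm_questionnaire_of(data)
  codes <- q$code[q$polarity == polarity & q$response_kind == "slider_0_100"]
  if (!length(codes)) rlang::abort(glue::glue("no slider items with polarity '{polarity}'"))
  m <- as.matrix(as.data.frame(data)[, codes, drop = FALSE])
  value <- rowMeans(m, na.rm = TRUE)
  value[!is.finite(value)] <- NA_real_
  tibble::tibble(time = data$time, date = data$date, slot = data$slot, value = value)
}

#' Flag candidate relapse episodes
#'
#' Smooths the negative composite and flags maximal windows in which the
#' smoothed series exceeds `global median + k_sd * robust sd` (robust sd =
#' 1.4826 x median absolute deviation) for at least `min_days` days.
#' Median/MAD are used so the threshold is not dragged up by the episodes
#' themselves. This is a descriptive screen to direct visual attention,
#' not a change-point model.
#'
#' @param data An `esm_df`.
#' @param k_sd Threshold height in robust standard deviations.
#' @param min_days Minimum exceedance duration, in days.
#' @param bandwidth Smoother bandwidth for the detection curve (same
#'   default as the display smoother).
#' @return A tibble of class `esm_episodes` with columns `start`, `end`
#'   (dates), `n_prompts`, `peak`; attributes carry the threshold used.
#' @export
flag_episodes <- function(data, k_sd = 2, min_days = 7, bandwidth = 0.2) {
  if (k_sd <= 0) rlang::abort("k_sd must be > 0")
  if (min_days < 1) rlang::abort("min_days must be >= 1")
  comp <- composite_series(data, "negative")
  ok <- !is.na(comp$value)
  empty <- structure(
    tibble::tibble(start = as.Date(character()), end = as.Date(character()),
                   n_prompts = integer(), peak = numeric()),
    threshold = NA_real_, class = c("esm_episodes", class(tibble::tibble())))
  if (sum(ok) < 3) return(empty)
  sm <- loess_smooth(comp$time[ok], comp$value[ok], bandwidth = bandwidth)
  med <- median(sm$fitted)
  rsd <- mad(sm$fitted)  # 1.4826 * MAD
  threshold <- med + k_sd * rsd
  above <- sm$fitted > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- purrr::map_dfr(which(runs$values), function(r) {
    i <- starts[r]:ends[r]
    tibble::tibble(
      start = as.Date(min(sm$time[i]), tz = "UTC"),
      end = as.Date(max(sm$time[i]), tz = "UTC"),
      n_prompts = length(i), peak = max(sm$fitted[i]))
  })
  if (nrow(out)) {
    out <- out[as.numeric(out$end - out$start) >= min_days, , drop = FALSE]
  } else {
    out <- empty
  }
  structure(dplyr::arrange(tibble::as_tibble(out), .data$start),
            threshold = threshold, k_sd = k_sd, min_days = min_days,
            bandwidth = bandwidth,
            class = c("esm_episodes", class(tibble::tibble())))
}

#' Missingness summary of an ESM dataset
#'
#' Quantifies when and how much the participant did not respond: per-item
#' missing fractions, per-day answered-prompt counts, and the maximal runs
#' of consecutive unanswered prompts.
#'
#' @param data An `esm_df`.
#' @return A list of class `esm_missingness` with tibbles `items` (`item`,
#'   `n_missing`, `n_observed`, `fraction`), `daily` (`date`,
#'   `n_answered`), and `gaps` (`start`, `end`, `n_prompts`).
#' @export
missingness_summary <- function(data) {
  q <- esm_questionnaire_of(data)
  n <- nrow(data)
  items <- purrr::map_dfr(q$code, function(code) {
    miss <- sum(is.na(data[[code]]))
    tibble::tibble(item = code, n_missing = miss, n_observed = n - miss,
                   fraction = if (n) miss / n else 0)
  })
  daily <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(data), .data$date),
                            n_answered = sum(.data$answered), .groups = "drop")
  runs <- rle(!data$answered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gaps <- purrr::map_dfr(which(runs$values), function(r) {
    tibble::tibble(start = data$time[starts[r]], end = data$time[ends[r]],
                   n_prompts = runs$lengths[r])
  })
  if (!nrow(gaps)) {
    gaps <- tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                           end = as.POSIXct(character(), tz = "UTC"),
                           n_prompts = integer())
  }
  structure(list(items = items, daily = daily, gaps = gaps),
            class = "esm_missingness")
}

#' @export
print.esm_missingness <- function(x, ...) {
  cat("<esm_missingness> mean item missing fraction",
      round(mean(x$items$fraction), 3), "|", nrow(x$gaps), "gap run(s)\n")
  invisible(x)
}
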