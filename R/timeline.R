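#' Two-panel smoothed timeline of all mood items
#'
#' Smoothed curves (see [loess_smooth()]) for every negative item in the
#' left panel and every positive item in the right panel, over the whole
#' study. Unanswered prompts are marked as rug ticks along the time axis
#' so missed periods are visible, and an optional raw-data overlay guards
#' against over-smoothing. An optional highlight window (e.g. the week a
#' movie frame focuses on) is drawn as a translucent blue overlay.
#'
#' @param data An `esm_df`.
#' @param bandwidth Smoother bandwidth, in (0, 1].
#' @param highlight Optional `c(start, end)` dates for the blue overlay.
#' @param show_raw Overlay the raw points (small, translucent).
#' @param items Optional subset of item codes to show.
#' @param colours Polarity colour overrides, see [polarity_colours()].
#' @return A ggplot object.
#' @export
plot_timeline <- function(data, bandwidth = 0.2, highlight = NULL,
                          show_raw = FALSE, items = NULL,
                          colours = polarity_colours()) {
  if (sum(data$answered) < 3) rlang::abort("need at least 3 answered prompts")
  curves <- smooth_items(data, items = items, bandwidth = bandwidth)
  if (!nrow(curves)) rlang::abort("no item has enough data to smooth")
  curves$polarity <- factor(curves$polarity, levels = c("negative", "positive"))
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$fitted,
                                            colour = .data$item))
  if (!is.null(highlight)) {
    hl <- as.POSIXct(paste(as.Date(highlight), c("00:00", "23:59")), tz = "UTC")
    w <- study_window(data)
    if (as.Date(hl[1]) < w[1] - 7 || as.Date(hl[2]) > w[2] + 7) {
      rlang::abort("highlight window outside the study range")
    }
    p <- p + ggplot2::annotate("rect", xmin = hl[1], xmax = hl[2],
                               ymin = -Inf, ymax = Inf,
                               fill = "#4C86C6", alpha = 0.22)
  }
  if (show_raw) {
    q <- esm_questionnaire_of(data)
    raw <- tidyr::pivot_longer(
      tibble::as_tibble(data)[, c("time", unique(curves$item))],
      cols = -"time", names_to = "item", values_to = "value")
    raw <- raw[!is.na(raw$value), , drop = FALSE]
    raw$polarity <- factor(q$polarity[match(raw$item, q$code)],
                           levels = c("negative", "positive"))
    p <- p + ggplot2::geom_point(data = raw,
                                 ggplot2::aes(y = .data$value), size = 0.4, alpha = 0.25)
  }
  gaps <- tibble::as_tibble(data)[!data$answered, "time"]
  if (nrow(gaps)) {
    p <- p + ggplot2::geom_rug(data = gaps, ggplot2::aes(x = .data$time),
                               inherit.aes = FALSE, sides = "b",
                               colour = "grey55", length = ggplot2::unit(0.02, "npc"))
  }
  p +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~polarity, nrow = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "score (0-100)", colour = NULL,
                  caption = paste0("smoothed curves, bandwidth ", bandwidth,
                                   "; ticks mark unanswered prompts")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom",
                   legend.text = ggplot2::element_text(size = 7))
}

#' Render the timeline or boxplot panel to PNG
#'
#' Thin file-writing wrappers over [plot_timeline()] and
#' [plot_boxplots()].
#'
#' @param data An `esm_df`.
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @param ... Passed to the plotting function.
#' @return `path`, invisibly.
#' @export
render_timeline <- function(data, path, width = 1400, height = 500, ...) {
  p <- plot_timeline(data, ...)
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

#' Polarity-coloured boxplot panel
#'
#' Boxplots (median, quartile box, 1.5 x IQR whiskers, outlier dots) of
#' every unconditional positive/negative slider item, ordered on median
#' within each polarity group. Event and count items, which are not asked
#' at every prompt, are excluded.
#'
#' @param data An `esm_df`.
#' @param direction Median ordering, `"asc"` (default) or `"desc"`.
#' @param colours Polarity colour overrides.
#' @return A ggplot object.
#' @export
plot_boxplots <- function(data, direction = "asc", colours = polarity_colours()) {
  autoplot(item_summaries(data), direction = direction, colours = colours)
}

#' @rdname render_timeline
#' @export
render_boxplots <- function(data, path, width = 1100, height = 500, ...) {
  p <- plot_boxplots(data, ...)
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
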