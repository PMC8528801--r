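#' Tidy and summarize fitted esmviz objects
#'
#' broom-style methods: `tidy()` returns one row per element (grid point,
#' flagged window, item), `glance()` a one-row summary.
#'
#' @param x An `esm_smooth`, `esm_episodes`, `esm_boxstats` or
#'   `esm_missingness` object.
#' @param ... Unused.
#' @return A tibble.
#' @name esmviz-tidiers
NULL

#' @rdname esmviz-tidiers
#' @export
tidy.esm_smooth <- function(x, ...) {
  tibble::tibble(item = attr(x, "item"), time = x$time, fitted = x$fitted)
}

#' @rdname esmviz-tidiers
#' @export
glance.esm_smooth <- function(x, ...) {
  tibble::tibble(item = attr(x, "item"), bandwidth = attr(x, "bandwidth"),
                 n = attr(x, "n"), n_grid = nrow(x))
}

#' @rdname esmviz-tidiers
#' @export
tidy.esm_episodes <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname esmviz-tidiers
#' @export
glance.esm_episodes <- function(x, ...) {
  tibble::tibble(n_episodes = nrow(x), threshold = attr(x, "threshold"),
                 k_sd = attr(x, "k_sd"), min_days = attr(x, "min_days"),
                 bandwidth = attr(x, "bandwidth"))
}

#' @rdname esmviz-tidiers
#' @export
tidy.esm_boxstats <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_outliers <- purrr::map_int(out$outliers, length)
  out
}

#' @rdname esmviz-tidiers
#' @export
tidy.esm_missingness <- function(x, ...) x$items

#' @rdname esmviz-tidiers
#' @export
glance.esm_missingness <- function(x, ...) {
  tibble::tibble(
    n_prompts = sum(x$daily$n_answered) + sum(x$gaps$n_prompts),
    n_gaps = nrow(x$gaps),
    longest_gap_prompts = if (nrow(x$gaps)) max(x$gaps$n_prompts) else 0L,
    mean_item_missing = mean(x$items$fraction))
}

#' Polarity colours
#'
#' Pink for negative (symptom) items, blue for positive (resilience)
#' items, grey for neutral context.
#' @param ... Named overrides, e.g. `negative = "#CC0066"`.
#' @return Named character vector of hex colours.
#' @export
polarity_colours <- function(...) {
  cols <- c(negative = "#E8638C", positive = "#4C86C6",
            neutral = "#9AA0A6", event = "#8B7355")
  over <- c(...)
  cols[names(over)] <- over
  cols
}

#' @rdname esmviz-tidiers
#' @param object An `esm_boxstats` object.
#' @export
autoplot.esm_boxstats <- function(object, ..., direction = "asc",
                                  colours = polarity_colours()) {
  ord <- order_items_by_median(object, direction = direction)
  df <- tibble::as_tibble(object)
  df$item <- factor(df$item, levels = ord)
  outs <- tidyr::unnest(dplyr::select(df, "item", "polarity", "outliers"),
                        cols = "outliers")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high, fill = .data$polarity),
      stat = "identity", width = 0.6) +
    ggplot2::geom_point(data = outs, ggplot2::aes(y = .data$outliers),
                        shape = 1, size = 1.2) +
    ggplot2::scale_fill_manual(values = colours) +
    ggplot2::facet_grid(. ~ polarity, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "score (0-100)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname esmviz-tidiers
#' @export
autoplot.esm_missingness <- function(object, ...) {
  ggplot2::ggplot(object$daily, ggplot2::aes(.data$date, .data$n_answered)) +
    ggplot2::geom_col(fill = "#4C86C6") +
    ggplot2::labs(x = NULL, y = "answered prompts / day") +
    ggplot2::theme_minimal()
}
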