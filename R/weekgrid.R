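#' Circle-glyph grid for one week
#'
#' Lays one ISO week (Monday start) out as 3 slot rows (morning /
#' afternoon / evening) by 7 weekday columns of circle-glyph specs.
#' Prompts outside the study window are blank cells; unanswered prompts
#' within the window get the explicit "no response" glyph.
#'
#' @param data An `esm_df` with the default 3-slot schedule.
#' @param week_start Any date inside the wanted week; snapped to its
#'   Monday.
#' @return A tibble of class `esm_week_grid` with columns `slot`,
#'   `weekday` (factor Mon..Sun), `date`, `spec` (list of
#'   `esm_circle_spec` or `NULL` for blank cells).
#' @export
build_week_grid <- function(data, week_start) {
  schedule <- esm_schedule_of(data)
  slots <- slot_names(schedule)
  q <- esm_questionnaire_of(data)
  monday <- monday_of(as.Date(week_start))
  w <- study_window(data)
  days <- monday + 0:6
  cells <- tidyr::expand_grid(slot = factor(slots, levels = slots),
                              date = days)
  cells$weekday <- factor(format(cells$date, "%a"),
                          levels = format(monday + 0:6, "%a"))
  cells$spec <- purrr::map2(cells$date, cells$slot, function(d, s) {
    if (d < w[1] || d > w[2]) return(NULL)
    row <- data[data$date == d & data$slot == s, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    build_circle_spec(row[1, ], q)
  })
  structure(cells[, c("slot", "weekday", "date", "spec")],
            week_start = monday,
            class = c("esm_week_grid", class(tibble::tibble())))
}

monday_of <- function(date) date - (as.integer(format(date, "%u")) - 1L)

# Mondays of all ISO weeks intersecting the study window
study_week_starts <- function(data) {
  w <- study_window(data)
  seq(monday_of(w[1]), monday_of(w[2]), by = "7 days")
}

# draw a built week grid into the current viewport
draw_week_grid <- function(grid_spec, label_nodes = FALSE, cex = 1,
                           background = NA) {
  slots <- levels(grid_spec$slot)
  wdays <- levels(grid_spec$weekday)
  lay <- grid::grid.layout(
    nrow = length(slots) + 1, ncol = length(wdays) + 1,
    widths = grid::unit(c(rep(1, length(wdays)), 0.35), "null"),
    heights = grid::unit(c(0.22, rep(1, length(slots))), "null"))
  if (!is.na(background)) {
    grid::grid.rect(gp = grid::gpar(col = NA, fill = background))
  }
  grid::pushViewport(grid::viewport(layout = lay))
  for (j in seq_along(wdays)) {
    grid::pushViewport(grid::viewport(layout.pos.row = 1, layout.pos.col = j))
    d <- grid_spec$date[grid_spec$weekday == wdays[j]][1]
    grid::grid.text(paste0(wdays[j], " ", format(d, "%d %b")),
                    gp = grid::gpar(cex = 0.7 * cex))
    grid::popViewport()
  }
  for (i in seq_along(slots)) {
    grid::pushViewport(grid::viewport(layout.pos.row = i + 1,
                                      layout.pos.col = length(wdays) + 1))
    grid::grid.text(slots[i], rot = 270, gp = grid::gpar(cex = 0.7 * cex))
    grid::popViewport()
    for (j in seq_along(wdays)) {
      cell <- grid_spec$spec[grid_spec$slot == slots[i] &
                               grid_spec$weekday == wdays[j]][[1]]
      if (is.null(cell)) next
      grid::pushViewport(grid::viewport(layout.pos.row = i + 1, layout.pos.col = j))
      grid::pushViewport(grid::viewport(width = grid::unit(0.94, "snpc"),
                                        height = grid::unit(0.94, "snpc")))
      draw_circle_glyph(cell, label_nodes = label_nodes, cex = 0.8 * cex)
      grid::popViewport(2)
    }
  }
  grid::popViewport()
  invisible(NULL)
}

#' Render a week grid to PNG
#'
#' @param grid_spec An `esm_week_grid` from [build_week_grid()].
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @param label_nodes Draw item codes around each glyph (off by default:
#'   the legend carries the codes).
#' @return `path`, invisibly.
#' @export
render_week_grid <- function(grid_spec, path, width = 1400, height = 640,
                             label_nodes = FALSE) {
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  grid::grid.newpage()
  draw_week_grid(grid_spec, label_nodes = label_nodes)
  invisible(path)
}

#' Poster of all responses
#'
#' Writes a multi-page PDF stacking every study week's circle-figure grid
#' in chronological order — the printout used in feedback sessions to
#' extract better and worse periods at a glance. With `tint = TRUE` each
#' week block gets a pale background from blue to pink according to that
#' week's mean negative composite, making difficult periods stand out
#' even at poster distance.
#'
#' @param data An `esm_df`.
#' @param path Output PDF path.
#' @param weeks_per_page Week grids stacked per page.
#' @param tint Tint week backgrounds by the weekly negative composite.
#' @return Invisibly, a list with `path`, `n_weeks`, `n_pages`.
#' @export
make_poster <- function(data, path, weeks_per_page = 4, tint = FALSE) {
  weeks <- study_week_starts(data)
  n_pages <- ceiling(length(weeks) / weeks_per_page)
  shades <- NULL
  if (tint) {
    comp <- composite_series(data, "negative")
    wk <- monday_of(comp$date)
    mean_by_week <- tapply(comp$value, wk, mean, na.rm = TRUE)
    v <- mean_by_week[as.character(weeks)]
    rng <- range(v, na.rm = TRUE)
    f <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, length(v))
    pal <- grDevices::colorRampPalette(c("#EAF1FA", "#FBE9F0"))(101)
    shades <- ifelse(is.na(f), NA, pal[round(f * 100) + 1])
  }
  grDevices::pdf(path, width = 11.7, height = 16.5, onefile = TRUE)  # A3 portrait
  on.exit(grDevices::dev.off(), add = TRUE)
  for (p in seq_len(n_pages)) {
    grid::grid.newpage()
    idx <- ((p - 1) * weeks_per_page + 1):min(p * weeks_per_page, length(weeks))
    lay <- grid::grid.layout(nrow = weeks_per_page, ncol = 1)
    grid::pushViewport(grid::viewport(layout = lay, width = 0.96, height = 0.97))
    for (k in seq_along(idx)) {
      grid::pushViewport(grid::viewport(layout.pos.row = k, layout.pos.col = 1))
      g <- build_week_grid(data, weeks[idx[k]])
      draw_week_grid(g, cex = 0.75,
                     background = if (is.null(shades)) NA else shades[idx[k]])
      grid::popViewport()
    }
    grid::popViewport()
  }
  invisible(list(path = path, n_weeks = length(weeks), n_pages = n_pages))
}
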