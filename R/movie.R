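#' Plan the per-week movie frames
#'
#' One frame per ISO week intersecting the study window, chronological:
#' each frame pairs the full-study timeline — with a translucent blue
#' overlay on the frame's week — with that week's circle-figure grid, so
#' the macro trajectory and the micro measurements are visible together.
#'
#' @param data An `esm_df`.
#' @param bandwidth Timeline smoother bandwidth.
#' @return A tibble of class `esm_frames`: `week_index`, `week_start`,
#'   `week_end` (the overlay window equals the grid week by
#'   construction); attribute `bandwidth`.
#' @export
build_week_frames <- function(data, bandwidth = 0.2) {
  weeks <- study_week_starts(data)
  structure(
    tibble::tibble(week_index = seq_along(weeks),
                   week_start = weeks, week_end = weeks + 6),
    bandwidth = bandwidth,
    class = c("esm_frames", class(tibble::tibble())))
}

# render one combined macro/micro frame (timeline top, week grid bottom)
render_frame <- function(data, week_start, path, bandwidth = 0.2,
                         width = 1200, height = 900, timeline = NULL) {
  week_start <- monday_of(as.Date(week_start))
  p <- timeline %||% plot_timeline(data, bandwidth = bandwidth)
  p <- p + ggplot2::annotate(
    "rect",
    xmin = as.POSIXct(paste(week_start, "00:00"), tz = "UTC"),
    xmax = as.POSIXct(paste(week_start + 6, "23:59"), tz = "UTC"),
    ymin = -Inf, ymax = Inf, fill = "#4C86C6", alpha = 0.22)
  g <- build_week_grid(data, week_start)
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  grid::grid.newpage()
  print(p, vp = grid::viewport(y = 1, height = 0.45, just = "top"))
  grid::pushViewport(grid::viewport(y = 0, height = 0.55, just = "bottom",
                                    width = 0.98))
  draw_week_grid(g, cex = 0.85)
  grid::popViewport()
  invisible(path)
}

#' Encode rendered frames into an animation
#'
#' @param frames Character vector of frame image paths (PNG), in order.
#' @param path Output path; must end in `.gif`. There is no MP4 encoder in
#'   this package, so asking for `.mp4` raises an error pointing at the
#'   GIF fallback.
#' @param fps Frames per second.
#' @return Invisibly, the [write_gif()] result.
#' @export
encode_video <- function(frames, path, fps = 1) {
  if (!length(frames)) rlang::abort("encode_video: need at least one frame")
  ext <- tolower(tools::file_ext(path))
  if (ext != "gif") {
    rlang::abort(glue::glue(
      "no encoder available for '.{ext}' output; use the GIF fallback (a path ending in .gif)"))
  }
  write_gif(as.list(frames), path, fps = fps)
}

#' Render and encode the whole per-week movie
#'
#' Convenience pipeline: [build_week_frames()], render every frame, then
#' [encode_video()].
#'
#' @param data An `esm_df`.
#' @param path Output `.gif` path.
#' @param bandwidth Timeline smoother bandwidth.
#' @param fps Frames per second (default 1: one study week per second).
#' @param width,height Frame size in pixels.
#' @return Invisibly, a list with `path`, `n_frames`, `width`, `height`.
#' @export
esm_movie <- function(data, path, bandwidth = 0.2, fps = 1,
                      width = 1200, height = 900) {
  frames <- build_week_frames(data, bandwidth = bandwidth)
  base <- plot_timeline(data, bandwidth = bandwidth)
  dir <- tempfile("frames")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- purrr::map_chr(seq_len(nrow(frames)), function(i) {
    fp <- file.path(dir, sprintf("frame_%03d.png", i))
    render_frame(data, frames$week_start[i], fp, bandwidth = bandwidth,
                 width = width, height = height, timeline = base)
    fp
  })
  out <- encode_video(paths, path, fps = fps)
  invisible(out)
}
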