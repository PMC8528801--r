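#' Resolve one prompt into a circle-glyph specification
#'
#' The circle figure shows everything a single prompt recorded at once.
#' Unconditional positive/negative slider items become nodes on a ring:
#' negative items occupy the left half, positive items the right, each arc
#' starting at 12 o'clock and evenly spaced in questionnaire order. A
#' node's fill fraction is `value / 100` — a completely grey node means a
#' score of zero (or no answer), a completely coloured node a score of
#' 100. Everything else becomes a centre badge: sleep (an "S", shaded
#' green by sleep quality), company, cancelled appointments (a square with
#' a "c"), the safe-contact count digit, and pleasant/unpleasant events
#' shaded by intensity. Free-text comments attach as a text box.
#'
#' @param record A one-row slice of an `esm_df` (one prompt).
#' @param questionnaire The matching [esm_questionnaire()]; defaults to
#'   the one stored on `record` when it is an `esm_df` slice.
#' @return A list of class `esm_circle_spec` with elements `time`, `slot`,
#'   `answered`, `comment`, `nodes` (tibble: `item`, `angle` in degrees
#'   clockwise from 12 o'clock, `radius`, `fill_fraction`, `colour`,
#'   `missing`) and `badges` (tibble: `kind`, `present`, `intensity`,
#'   `glyph`).
#' @export
build_circle_spec <- function(record, questionnaire = NULL) {
  questionnaire <- questionnaire %||% esm_questionnaire_of(record)
  if (is.null(questionnaire)) rlang::abort("no questionnaire available for record")
  q <- questionnaire
  if (nrow(record) != 1) rlang::abort("record must be a single prompt (one row)")
  cols <- polarity_colours()

  ring <- ring_codes(q)
  pol <- q$polarity[match(ring, q$code)]
  neg <- ring[pol == "negative"]
  pos <- ring[pol == "positive"]
  # negative arc fills the left half (12 going counterclockwise), positive
  # the right half (12 going clockwise); angles in degrees clockwise from 12
  ang <- c(setNames(360 - (seq_along(neg) - 0.5) * 180 / max(length(neg), 1), neg),
           setNames((seq_along(pos) - 0.5) * 180 / max(length(pos), 1), pos))
  nodes <- purrr::map_dfr(ring, function(code) {
    v <- record[[code]]
    tibble::tibble(
      item = code,
      angle = unname(ang[code]),
      radius = 1,
      fill_fraction = if (is.na(v)) 0 else v / 100,
      colour = unname(cols[q$polarity[q$code == code]]),
      missing = is.na(v))
  })

  badges <- build_badges(record, q)

  structure(list(
    time = record$time, slot = as.character(record$slot),
    answered = isTRUE(record$answered),
    comment = if (is.na(record$comment)) NULL else record$comment,
    nodes = nodes, badges = badges),
    class = "esm_circle_spec")
}

# canonical badge kinds for the packaged questionnaire; other
# questionnaires fall back to the item code as the kind
badge_kind <- function(code) {
  switch(code,
    Slept = "sleep", Comp = "company", Canc = "cancelled_appointment",
    Cont = "contact_count", Pleas = "pleasant_event", Unpl = "unpleasant_event",
    code)
}

build_badges <- function(record, q) {
  ring <- ring_codes(q)
  rows <- list()
  add <- function(kind, present, intensity, glyph) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      kind = kind, present = present, intensity = intensity, glyph = glyph)
  }
  handled <- character()
  for (i in seq_len(nrow(q))) {
    code <- q$code[i]
    if (code %in% c(ring, handled)) next
    kind <- q$response_kind[i]
    v <- record[[code]]
    if (kind == "likert_count") {
      present <- !is.na(v) && v > 0
      add(badge_kind(code), present, NA_real_,
          if (present) as.character(v) else NA_character_)
    } else if (kind == "yes_no" && q$polarity[i] != "event") {
      child <- q$code[!is.na(q$conditional_on) & q$conditional_on == code]
      present <- !is.na(v) && v == "yes"
      intensity <- NA_real_
      if (length(child)) {
        cv <- record[[child[1]]]
        if (present && !is.na(cv)) intensity <- cv / 100
        handled <- c(handled, child)
      }
      add(badge_kind(code), present, intensity, toupper(substr(code, 1, 1)))
    } else if (kind == "yes_no" && q$polarity[i] == "event") {
      kids <- q$code[!is.na(q$conditional_on) & q$conditional_on == code]
      for (kid in kids) {
        cv <- record[[kid]]
        add(badge_kind(kid), !is.na(cv), if (is.na(cv)) NA_real_ else cv / 100,
            if (badge_kind(kid) == "unpleasant_event") "-" else "+")
        handled <- c(handled, kid)
      }
      handled <- c(handled, code)
    } else if (kind == "slider_0_100" && is.na(q$conditional_on[i])) {
      # event-polarity unconditional slider (unusual): shaded badge
      add(badge_kind(code), !is.na(v), if (is.na(v)) NA_real_ else v / 100,
          toupper(substr(code, 1, 1)))
    }
  }
  add("comment", !is.na(record$comment), NA_real_, NA_character_)
  out <- dplyr::bind_rows(rows)
  # cancelled-appointment badge draws a lowercase c in a square
  out$glyph[out$kind == "cancelled_appointment"] <- "c"
  out
}

badge_shade <- function(kind, intensity) {
  ramps <- list(
    sleep = c("#E8F5E9", "#1B5E20"),
    pleasant_event = c("#E3F2FD", "#0D47A1"),
    unpleasant_event = c("#FCE4EC", "#880E4F"))
  ramp <- ramps[[kind]] %||% c("#F5F5F5", "#424242")
  if (is.na(intensity)) return("#FFFFFF")
  grDevices::colorRampPalette(ramp)(101)[round(intensity * 100) + 1]
}

# polygon of the part of a disc lying below a horizontal fill level
fill_polygon <- function(cx, cy, r, f, n = 72) {
  u <- 2 * f - 1
  a <- asin(pmin(1, pmax(-1, u)))
  theta <- seq(pi - a, 2 * pi + a, length.out = n)
  list(x = cx + r * cos(theta), y = cy + r * sin(theta))
}

# draw one circle glyph into the current (square) grid viewport
draw_circle_glyph <- function(spec, label_nodes = TRUE,
                              distinguish_missing = FALSE, cex = 1) {
  if (!spec$answered) {
    grid::grid.circle(0.5, 0.5, r = 0.38,
                      gp = grid::gpar(col = "grey60", fill = NA, lty = "dashed", lwd = 1.2))
    grid::grid.text("no\nresponse", 0.5, 0.5,
                    gp = grid::gpar(col = "grey50", cex = 0.7 * cex))
    return(invisible(NULL))
  }
  grid::grid.circle(0.5, 0.5, r = 0.38, gp = grid::gpar(col = "grey80", fill = NA, lwd = 0.6))

  ring_r <- 0.38; node_r <- 0.052
  for (i in seq_len(nrow(spec$nodes))) {
    nd <- spec$nodes[i, ]
    rad <- (90 - nd$angle) * pi / 180  # clockwise-from-12 -> math angle
    cx <- 0.5 + ring_r * cos(rad)
    cy <- 0.5 + ring_r * sin(rad)
    grid::grid.circle(cx, cy, r = node_r,
                      gp = grid::gpar(col = "grey55", fill = "grey85", lwd = 0.5))
    if (nd$fill_fraction > 0) {
      pg <- fill_polygon(cx, cy, node_r, min(1, nd$fill_fraction))
      grid::grid.polygon(pg$x, pg$y, gp = grid::gpar(col = NA, fill = nd$colour))
    }
    if (nd$missing && distinguish_missing) {
      grid::grid.segments(cx - node_r, cy - node_r, cx + node_r, cy + node_r,
                          gp = grid::gpar(col = "grey40", lwd = 0.8))
    }
    if (label_nodes) {
      lx <- 0.5 + (ring_r + 0.085) * cos(rad)
      ly <- 0.5 + (ring_r + 0.085) * sin(rad)
      grid::grid.text(nd$item, lx, ly, gp = grid::gpar(cex = 0.55 * cex, col = "grey30"))
    }
  }

  drawable <- spec$badges[spec$badges$kind != "comment", , drop = FALSE]
  slots <- badge_slots(nrow(drawable))
  for (i in seq_len(nrow(drawable))) {
    b <- drawable[i, ]
    if (!b$present) next
    bx <- slots$x[i]; by <- slots$y[i]; half <- 0.055
    if (b$kind == "contact_count") {
      grid::grid.text(b$glyph, bx, by, gp = grid::gpar(cex = 0.9 * cex, fontface = "bold"))
    } else {
      shaded <- b$kind %in% c("sleep", "pleasant_event", "unpleasant_event")
      fill <- if (shaded) badge_shade(b$kind, b$intensity) else "#FFFFFF"
      grid::grid.rect(bx, by, width = 2 * half, height = 2 * half,
                      gp = grid::gpar(col = "grey35", fill = fill, lwd = 0.7))
      dark <- shaded && !is.na(b$intensity) && b$intensity > 0.55
      grid::grid.text(b$glyph, bx, by,
                      gp = grid::gpar(cex = 0.7 * cex,
                                      col = if (dark) "white" else "grey15"))
    }
  }

  cm <- spec$badges[spec$badges$kind == "comment", , drop = FALSE]
  if (nrow(cm) && cm$present[1]) {
    grid::grid.circle(0.5, 0.085, r = 0.025,
                      gp = grid::gpar(col = NA, fill = "#F9A825"))
  }
  invisible(NULL)
}

# fixed centre positions for up to 9 badges (row-major mini-grid)
badge_slots <- function(n) {
  if (n == 0) return(list(x = numeric(), y = numeric()))
  ncol <- min(3, n)
  nrow <- ceiling(n / 3)
  ix <- (seq_len(n) - 1) %% 3
  iy <- (seq_len(n) - 1) %/% 3
  list(x = 0.5 + (ix - (ncol - 1) / 2) * 0.14,
       y = 0.5 + ((nrow - 1) / 2 - iy) * 0.14)
}

#' Render a circle glyph to PNG
#'
#' Rendering is deterministic: the same spec always produces the same
#' bytes (fixed device, fonts and geometry, no randomness).
#'
#' @param spec An `esm_circle_spec` from [build_circle_spec()].
#' @param path Output PNG path.
#' @param size Image width/height in pixels.
#' @param distinguish_missing Draw missing nodes with a diagonal tick so
#'   they can be told apart from true zeros (off by default, matching the
#'   classic legend where grey is ambiguous).
#' @return `path`, invisibly.
#' @export
render_circle <- function(spec, path, size = 480, distinguish_missing = FALSE) {
  has_comment <- !is.null(spec$comment)
  height <- if (has_comment) round(size * 1.2) else size
  grDevices::png(path, width = size, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  grid::grid.newpage()
  main_h <- if (has_comment) size / height else 1
  grid::pushViewport(grid::viewport(y = 1, height = main_h, just = "top"))
  grid::grid.text(paste(format(spec$time, "%a %d %b %Y %H:%M")),
                  0.5, 0.97, gp = grid::gpar(cex = 0.8, col = "grey30"))
  grid::pushViewport(grid::viewport(y = 0.47, width = grid::unit(0.88, "snpc"),
                                    height = grid::unit(0.88, "snpc")))
  draw_circle_glyph(spec, distinguish_missing = distinguish_missing)
  grid::popViewport(2)
  if (has_comment) {
    grid::pushViewport(grid::viewport(y = 0, height = 1 - main_h, just = "bottom"))
    grid::grid.rect(0.5, 0.5, width = 0.92, height = 0.8,
                    gp = grid::gpar(col = "#F9A825", fill = "#FFF8E1"))
    grid::grid.text(wrap_text(spec$comment, 46), 0.5, 0.5,
                    gp = grid::gpar(cex = 0.75))
    grid::popViewport()
  }
  invisible(path)
}

wrap_text <- function(x, width) paste(strwrap(x, width = width), collapse = "\n")

#' Legend entries for the circle figure
#'
#' The layout-level description of the legend that accompanies every
#' feedback figure: one entry per ring item (code and full label, with its
#' polarity colour), one per badge kind, and the caveat that a grey node
#' or an absent badge can mean either "not filled in" or a true
#' zero/absent answer.
#'
#' @param questionnaire An [esm_questionnaire()].
#' @return A tibble with columns `entry` (`node`/`badge`/`colour`/`note`),
#'   `code`, `text`.
#' @export
legend_spec <- function(questionnaire) {
  q <- questionnaire
  ring <- ring_codes(q)
  nodes <- tibble::tibble(
    entry = "node", code = ring,
    text = q$label[match(ring, q$code)])
  sample_rec <- blank_record(q)
  badges <- build_badges(sample_rec, q)
  badge_text <- c(
    sleep = "slept since last beep; green shade = sleep quality",
    company = "in company",
    cancelled_appointment = "actually cancelled an appointment",
    contact_count = "number of safe contacts (digit)",
    pleasant_event = "pleasant event; shade = intensity",
    unpleasant_event = "unpleasant event; shade = intensity",
    comment = "free-text comment attached")
  badges_tbl <- tibble::tibble(
    entry = "badge", code = badges$kind,
    text = unname(badge_text[badges$kind]) %|NA|% badges$kind)
  cols <- polarity_colours()
  colour_tbl <- tibble::tibble(
    entry = "colour", code = c("positive", "negative"),
    text = c(paste0("positive (resilience-related) items, blue ", cols[["positive"]]),
             paste0("negative (symptom-related) items, pink ", cols[["negative"]])))
  note <- tibble::tibble(
    entry = "note", code = NA_character_,
    text = paste("A grey node or an absent centre label can mean either that",
                 "the prompt was not filled in, or that the answer really was",
                 "zero / absent."))
  dplyr::bind_rows(nodes, badges_tbl, colour_tbl, note)
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

# an answered record with every value missing, used for layout resolution
blank_record <- function(q) {
  rec <- tibble::tibble(time = as.POSIXct("2017-03-01 09:00", tz = "UTC"),
                        slot = factor("morning"), answered = TRUE,
                        comment = NA_character_)
  for (i in seq_len(nrow(q))) {
    rec[[q$code[i]]] <- if (q$response_kind[i] %in% c("yes_no", "free_text")) {
      NA_character_
    } else NA_real_
  }
  rec
}

#' Render the circle-figure legend to PNG
#'
#' @param questionnaire An [esm_questionnaire()].
#' @param path Output PNG path.
#' @param size Image width in pixels.
#' @return `path`, invisibly.
#' @export
render_legend <- function(questionnaire, path, size = 900) {
  spec <- legend_spec(questionnaire)
  q <- questionnaire
  # a sample glyph: every node filled 70%, all badges present
  rec <- blank_record(q)
  for (code in ring_codes(q)) rec[[code]] <- 70
  for (i in seq_len(nrow(q))) {
    code <- q$code[i]
    if (code %in% ring_codes(q)) next
    rec[[code]] <- switch(q$response_kind[i],
      yes_no = "yes", likert_count = min(2, q$likert_max[i]),
      slider_0_100 = 70, free_text = NA_character_)
  }
  rec$comment <- "comments appear in a text box like this"
  glyph <- build_circle_spec(rec, q)

  lines <- c(
    paste0("  [", spec$code[spec$entry == "node"], "]  ",
           spec$text[spec$entry == "node"]),
    "", paste0("  ", spec$text[spec$entry == "colour"]),
    "", paste0("  (", spec$code[spec$entry == "badge"], ")  ",
               spec$text[spec$entry == "badge"]),
    "", wrap_text(spec$text[spec$entry == "note"], 60))
  height <- round(size * 0.62)
  grDevices::png(path, width = size, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  grid::grid.newpage()
  grid::pushViewport(grid::viewport(x = 0, width = 0.45, just = "left"))
  grid::pushViewport(grid::viewport(width = grid::unit(0.92, "snpc"),
                                    height = grid::unit(0.92, "snpc")))
  draw_circle_glyph(glyph)
  grid::popViewport(2)
  grid::pushViewport(grid::viewport(x = 0.45, width = 0.55, just = "left"))
  grid::grid.text(paste(lines, collapse = "\n"), x = 0.03, y = 0.97,
                  just = c("left", "top"), gp = grid::gpar(cex = 0.62))
  grid::popViewport()
  invisible(path)
}
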