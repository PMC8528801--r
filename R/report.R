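#' Client-side toggles of the interactive report
#'
#' The report replaces a live server app with a single self-contained
#' HTML document; these toggles set its initial state, and every one of
#' them remains switchable in the opened document.
#'
#' @param show_comments Include and show the patient's free-text comments.
#'   When `FALSE` the comment texts are left out of the document entirely.
#' @param visible_items Item codes whose curves are included; `NULL` means
#'   all ring items.
#' @param zoom Optional `c(start, end)` dates the timeline initially zooms
#'   to.
#' @param show_raw_overlay Start with the raw data points visible under
#'   the smoothed curves.
#' @return A list of class `esm_report_toggles`.
#' @export
report_toggles <- function(show_comments = TRUE, visible_items = NULL,
                           zoom = NULL, show_raw_overlay = FALSE) {
  structure(list(show_comments = isTRUE(show_comments),
                 visible_items = visible_items,
                 zoom = if (!is.null(zoom)) as.Date(zoom),
                 show_raw_overlay = isTRUE(show_raw_overlay)),
            class = "esm_report_toggles")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Build the self-contained interactive feedback report
#'
#' Writes one HTML file with no server or network dependency: the
#' smoothed two-panel timeline as inline SVG (curves per item, raw-point
#' overlay, unanswered-gap ticks), every week's circle-figure grid as an
#' embedded PNG, the free-text comments, and plain-JavaScript controls
#' for each [report_toggles()] field (per-item curve visibility, comment
#' visibility, raw overlay, and a date-range zoom). The numbers behind
#' the curves are exactly the [smooth_items()] output and are embedded as
#' JSON in the document.
#'
#' @param data An `esm_df`.
#' @param toggles A [report_toggles()].
#' @param path Output `.html` path.
#' @param bandwidth Smoother bandwidth.
#' @return Invisibly, `path`.
#' @export
build_report <- function(data, toggles = report_toggles(), path,
                         bandwidth = 0.2) {
  q <- esm_questionnaire_of(data)
  w <- study_window(data)
  items <- toggles$visible_items %||% ring_codes(q)
  items <- intersect(items, q$code)
  if (!length(items)) rlang::abort("no visible items")
  curves <- smooth_items(data, items = items, bandwidth = bandwidth)
  if (!nrow(curves)) rlang::abort("no item has enough data to smooth")

  day0 <- as.numeric(as.POSIXct(paste(w[1], "00:00"), tz = "UTC"))
  xday <- function(t) (as.numeric(t) - day0) / 86400
  n_days <- as.numeric(w[2] - w[1]) + 1

  pol_of <- function(code) q$polarity[q$code == code]
  colour_of <- function(code) unname(polarity_colours()[pol_of(code)])

  # per-item polyline points in (day, score) coordinates
  poly <- function(code) {
    cc <- curves[curves$item == code, , drop = FALSE]
    paste(sprintf("%.3f,%.2f", xday(cc$time), 100 - cc$fitted), collapse = " ")
  }
  raw_pts <- function(code) {
    keep <- !is.na(data[[code]])
    sprintf('<circle class="raw raw-%s" cx="%.3f" cy="%.2f" r="0.35" fill="%s" fill-opacity="0.35"/>',
            code, xday(data$time[keep]), 100 - data[[code]][keep], colour_of(code))
  }

  panel_svg <- function(polarity) {
    codes <- intersect(unique(curves$item),
                       q$code[q$polarity == polarity])
    gaps <- data$time[!data$answered]
    gap_marks <- if (length(gaps)) {
      sprintf('<rect class="gap" x="%.3f" y="98" width="0.28" height="4" fill="#999"/>',
              xday(gaps))
    } else character()
    lines <- purrr::map_chr(codes, function(code) {
      sprintf('<polyline class="curve curve-%s" points="%s" fill="none" stroke="%s" stroke-width="0.5" vector-effect="non-scaling-stroke"/>',
              code, poly(code), colour_of(code))
    })
    raws <- unlist(purrr::map(codes, raw_pts))
    glue::glue(
      '<div class="panel"><h3>{polarity} items</h3>',
      '<svg class="timeline" viewBox="0 -2 {n_days} 106" preserveAspectRatio="none">',
      '{paste(gap_marks, collapse = "")}',
      '{paste(raws, collapse = "")}',
      '{paste(lines, collapse = "")}',
      "</svg></div>")
  }

  # week grids as embedded PNGs
  weeks <- study_week_starts(data)
  grid_divs <- purrr::map_chr(seq_along(weeks), function(i) {
    fp <- tempfile(fileext = ".png")
    on.exit(unlink(fp), add = TRUE)
    render_week_grid(build_week_grid(data, weeks[i]), fp,
                     width = 1100, height = 500)
    b64 <- jsonlite::base64_enc(readBin(fp, "raw", file.info(fp)$size))
    glue::glue('<div class="week"><h4>week of {format(weeks[i], "%d %b %Y")}</h4>',
               '<img alt="week grid" src="data:image/png;base64,{gsub("\n", "", b64)}"/></div>')
  })

  comments_html <- ""
  if (toggles$show_comments) {
    cm <- tibble::as_tibble(data)[!is.na(data$comment), c("time", "comment")]
    rows <- if (nrow(cm)) {
      paste0("<li><b>", format(cm$time, "%d %b %Y %H:%M"), "</b> — ",
             html_escape(cm$comment), "</li>", collapse = "")
    } else "<li>(no comments)</li>"
    comments_html <- glue::glue(
      '<section id="comments"><h2>Comments</h2><ul>{rows}</ul></section>')
  }

  curve_json <- jsonlite::toJSON(list(
    bandwidth = bandwidth,
    study_start = as.character(w[1]),
    study_end = as.character(w[2]),
    items = purrr::map(setNames(items, items), function(code) {
      cc <- curves[curves$item == code, , drop = FALSE]
      list(polarity = pol_of(code),
           time = as.character(cc$time), fitted = cc$fitted)
    })), auto_unbox = TRUE, digits = 8)

  checkboxes <- paste(purrr::map_chr(intersect(unique(curves$item), items), function(code) {
    glue::glue('<label><input type="checkbox" class="item-toggle" data-item="{code}" checked> {code}</label>')
  }), collapse = "\n")

  zoom_start <- if (!is.null(toggles$zoom)) toggles$zoom[1] else w[1]
  zoom_end <- if (!is.null(toggles$zoom)) toggles$zoom[2] else w[2]

  html <- glue::glue('<!DOCTYPE html>
<html><head><meta charset="utf-8"><title>ESM feedback report</title>
<style>
body {{ font-family: sans-serif; margin: 1.5em; max-width: 1200px; }}
.panel {{ display: inline-block; width: 48%; vertical-align: top; }}
svg.timeline {{ width: 100%; height: 260px; background: #fafafa; border: 1px solid #ddd; }}
.week img {{ max-width: 100%; }}
#controls label {{ margin-right: 0.8em; }}
.hidden {{ display: none; }}
</style></head><body>
<h1>ESM feedback report</h1>
<p>Single-subject experience-sampling study, {format(w[1], "%d %b %Y")} &ndash; {format(w[2], "%d %b %Y")}.
Curves are locally weighted regression smooths (bandwidth {bandwidth}); grey ticks mark unanswered prompts.
A grey node or absent badge in the circle figures can mean "not filled in" as well as a true zero.</p>
<section id="controls">
<h2>Controls</h2>
<div>{checkboxes}</div>
<label><input type="checkbox" id="toggle-raw" {if (toggles$show_raw_overlay) "checked" else ""}> raw data overlay</label>
<label><input type="checkbox" id="toggle-comments" {if (toggles$show_comments) "checked" else ""} {if (!toggles$show_comments) "disabled" else ""}> show comments</label>
<label>zoom from <input type="date" id="zoom-start" value="{zoom_start}" min="{w[1]}" max="{w[2]}"></label>
<label>to <input type="date" id="zoom-end" value="{zoom_end}" min="{w[1]}" max="{w[2]}"></label>
<button id="zoom-apply">apply zoom</button>
<button id="zoom-reset">reset</button>
</section>
<section id="timeline">
<h2>Timeline</h2>
{panel_svg("negative")}
{panel_svg("positive")}
</section>
{comments_html}
<section id="weeks"><h2>Week by week</h2>
{paste(grid_divs, collapse = "\n")}
</section>
<script id="esm-data" type="application/json">{curve_json}</script>
<script>
(function() {{
  var dayMs = 86400000;
  var start = new Date("{w[1]}T00:00:00Z").getTime();
  var nDays = {n_days};
  function setViewBox(a, b) {{
    document.querySelectorAll("svg.timeline").forEach(function(s) {{
      s.setAttribute("viewBox", a + " -2 " + Math.max(1, b - a) + " 106");
    }});
  }}
  document.querySelectorAll(".item-toggle").forEach(function(cb) {{
    cb.addEventListener("change", function() {{
      var code = cb.getAttribute("data-item");
      document.querySelectorAll(".curve-" + code + ", .raw-" + code)
        .forEach(function(el) {{ el.classList.toggle("hidden", !cb.checked); }});
      syncRaw();
    }});
  }});
  var rawBox = document.getElementById("toggle-raw");
  function syncRaw() {{
    document.querySelectorAll(".raw").forEach(function(el) {{
      var code = el.getAttribute("class").match(/raw-(\\S+)/)[1];
      var cb = document.querySelector(".item-toggle[data-item=\'" + code + "\']");
      var on = rawBox.checked && (!cb || cb.checked);
      el.classList.toggle("hidden", !on);
    }});
  }}
  rawBox.addEventListener("change", syncRaw);
  syncRaw();
  var cBox = document.getElementById("toggle-comments");
  if (cBox) cBox.addEventListener("change", function() {{
    var sec = document.getElementById("comments");
    if (sec) sec.classList.toggle("hidden", !cBox.checked);
  }});
  function applyZoom() {{
    var a = (new Date(document.getElementById("zoom-start").value + "T00:00:00Z").getTime() - start) / dayMs;
    var b = (new Date(document.getElementById("zoom-end").value + "T00:00:00Z").getTime() - start) / dayMs + 1;
    setViewBox(Math.max(0, a), Math.min(nDays, b));
  }}
  document.getElementById("zoom-apply").addEventListener("click", applyZoom);
  document.getElementById("zoom-reset").addEventListener("click", function() {{
    document.getElementById("zoom-start").value = "{w[1]}";
    document.getElementById("zoom-end").value = "{w[2]}";
    setViewBox(0, nDays);
  }});
  applyZoom();
}})();
</script>
</body></html>')
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}
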