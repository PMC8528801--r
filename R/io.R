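#' Describe the tabular layout of an ESM response file
#'
#' Response tables come in two orientations: `wide` (one row per answered
#' prompt, one column per item — the canonical layout, matching the circle
#' figure's unit of display) and `long` (one row per prompt x item).
#' Timestamps are minute-resolution `"YYYY-MM-DD HH:MM"` local clock
#' times.
#'
#' @param orientation `"wide"` or `"long"`.
#' @param missing_codes Strings read as missing; the first is used when
#'   writing.
#' @param time_column,comment_column Column names for the prompt timestamp
#'   and the free-text comment.
#' @param item_column,value_column Column names used by the long
#'   orientation.
#' @return A list of class `esm_dialect`.
#' @export
esm_dialect <- function(orientation = c("wide", "long"),
                        missing_codes = c("", "NA"),
                        time_column = "time",
                        comment_column = "comment",
                        item_column = "item",
                        value_column = "value") {
  orientation <- rlang::arg_match(orientation)
  structure(list(orientation = orientation, missing_codes = missing_codes,
                 time_column = time_column, comment_column = comment_column,
                 item_column = item_column, value_column = value_column),
            class = "esm_dialect")
}

TIME_FMT <- "%Y-%m-%d %H:%M"

parse_times_checked <- function(x) {
  t <- as.POSIXct(x, tz = "UTC", format = TIME_FMT)
  bad <- which(is.na(t))
  if (length(bad)) {
    rlang::abort(glue::glue(
      "unparseable timestamp '{x[bad[1]]}' at data row {bad[1]} (expected YYYY-MM-DD HH:MM)"))
  }
  t
}

#' Read an ESM response table
#'
#' Reads a CSV of answered prompts and returns a validated [esm_dataset()]
#' in which every scheduled prompt of the study window is materialized:
#' prompts absent from the file become `answered = FALSE` rows, so
#' missingness is explicit in the returned data rather than implicit in
#' absent rows.
#'
#' @param path CSV file path.
#' @param questionnaire An [esm_questionnaire()].
#' @param schedule A [prompt_schedule()].
#' @param dialect An [esm_dialect()].
#' @param study_start,study_end Study window; defaults to the date range
#'   present in the file (must be given for a file with no data rows).
#' @return An `esm_df`.
#' @export
read_esm_csv <- function(path, questionnaire, schedule = prompt_schedule(),
                         dialect = esm_dialect(),
                         study_start = NULL, study_end = NULL) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0))
  raw <- tibble::as_tibble(raw)
  if (!dialect$time_column %in% names(raw)) {
    rlang::abort(glue::glue("column '{dialect$time_column}' not found in {path}"))
  }
  to_na <- function(x) replace(x, x %in% dialect$missing_codes, NA_character_)

  if (dialect$orientation == "wide") {
    items <- setdiff(names(raw), c(dialect$time_column, dialect$comment_column, "answered"))
    unknown <- setdiff(items, questionnaire$code)
    if (length(unknown)) {
      rlang::abort(glue::glue("unknown column(s) in {path}: {paste(unknown, collapse = ', ')}"))
    }
    rec <- tibble::tibble(time = parse_times_checked(raw[[dialect$time_column]]))
    for (code in items) rec[[code]] <- to_na(raw[[code]])
    rec$comment <- if (dialect$comment_column %in% names(raw)) {
      to_na(raw[[dialect$comment_column]])
    } else NA_character_
  } else {
    needed <- c(dialect$item_column, dialect$value_column)
    miss <- setdiff(needed, names(raw))
    if (length(miss)) {
      rlang::abort(glue::glue("column '{miss[1]}' not found in {path}"))
    }
    unknown <- setdiff(unique(raw[[dialect$item_column]]), questionnaire$code)
    if (length(unknown)) {
      rlang::abort(glue::glue("unknown item code(s) in {path}: {paste(unknown, collapse = ', ')}"))
    }
    long <- tibble::tibble(
      time = parse_times_checked(raw[[dialect$time_column]]),
      item = raw[[dialect$item_column]],
      value = to_na(raw[[dialect$value_column]]),
      comment = if (dialect$comment_column %in% names(raw)) {
        to_na(raw[[dialect$comment_column]])
      } else NA_character_)
    rec <- tidyr::pivot_wider(long, id_cols = "time",
                              names_from = "item", values_from = "value")
    cm <- dplyr::summarise(
      dplyr::group_by(long, .data$time),
      comment = dplyr::first(.data$comment[!is.na(.data$comment)], default = NA_character_))
    rec <- dplyr::left_join(rec, cm, by = "time")
  }

  esm_dataset(rec, questionnaire, schedule,
              study_start = study_start, study_end = study_end)
}

#' Write an ESM dataset to CSV
#'
#' Only answered prompts are written; unanswered prompts are re-created at
#' read time from the study window, so raw files stay minimal. Missing
#' values serialize as the dialect's first missing code, and yes/no answers
#' as the strings `"yes"`/`"no"` (never 0/1, which would collide with
#' count items). `read_esm_csv()` on the output (with the same study
#' window) reproduces the dataset exactly.
#'
#' @param data An `esm_df`.
#' @param path Output CSV path.
#' @param dialect An [esm_dialect()].
#' @return `path`, invisibly.
#' @export
write_esm_csv <- function(data, path, dialect = esm_dialect()) {
  q <- esm_questionnaire_of(data)
  ans <- data[data$answered, , drop = FALSE]
  na_code <- dialect$missing_codes[1]
  fmt <- function(x) {
    out <- as.character(x)
    replace(out, is.na(out), na_code)
  }

  if (dialect$orientation == "wide") {
    out <- tibble::tibble(.time = format(ans$time, TIME_FMT))
    names(out) <- dialect$time_column
    for (code in q$code) out[[code]] <- fmt(ans[[code]])
    out[[dialect$comment_column]] <- fmt(ans$comment)
  } else {
    chr <- tibble::tibble(.time = format(ans$time, TIME_FMT))
    for (code in q$code) chr[[code]] <- fmt(ans[[code]])
    chr$.comment <- fmt(ans$comment)
    long <- tidyr::pivot_longer(chr, cols = dplyr::all_of(q$code),
                                names_to = ".item", values_to = ".value")
    out <- long[, c(".time", ".item", ".value", ".comment")]
    names(out) <- c(dialect$time_column, dialect$item_column,
                    dialect$value_column, dialect$comment_column)
  }
  utils::write.csv(out, path, row.names = FALSE, na = na_code)
  invisible(path)
}
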