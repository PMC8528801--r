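#' Assemble an ESM dataset
#'
#' An ESM dataset is a wide tibble with one row per scheduled prompt —
#' answered or not — and one column per questionnaire item, carrying the
#' questionnaire, the prompt schedule and the study window as attributes.
#' Missingness is explicit: every prompt between `study_start` and
#' `study_end` is materialized, and unanswered prompts appear as rows with
#' `answered = FALSE` and all values `NA`. `NA` is a first-class "not
#' filled in" value, distinct from a recorded `0` or `"no"`.
#'
#' Duplicate submissions for the same `(date, slot)` prompt keep the first
#' row; the dropped rows are remembered and reported by
#' [validate_dataset()].
#'
#' @param records A data frame with a `time` column (`POSIXct` or
#'   parseable) plus item-code columns and optionally `comment` and
#'   `answered`.
#' @param questionnaire An [esm_questionnaire()].
#' @param schedule A [prompt_schedule()].
#' @param study_start,study_end Study window (`Date`); defaults to the
#'   date range present in `records`.
#' @return A tibble of class `esm_df` with columns `time`, `date`, `slot`,
#'   `answered`, one column per item code, and `comment`.
#' @export
esm_dataset <- function(records, questionnaire, schedule = prompt_schedule(),
                        study_start = NULL, study_end = NULL) {
  records <- tibble::as_tibble(records)
  if (!"time" %in% names(records)) rlang::abort("records must have a 'time' column")
  known <- c("time", "date", "slot", "answered", "comment", questionnaire$code)
  unknown <- setdiff(names(records), known)
  if (length(unknown)) {
    rlang::abort(glue::glue("unknown item column(s): {paste(unknown, collapse = ', ')}"))
  }

  records$time <- as.POSIXct(records$time, tz = "UTC")
  records$date <- as.Date(records$time, tz = "UTC")
  records$slot <- slot_of(records$time, schedule)
  if (!"comment" %in% names(records)) records$comment <- NA_character_
  if (!"answered" %in% names(records)) records$answered <- TRUE

  if (nrow(records) == 0 && (is.null(study_start) || is.null(study_end))) {
    rlang::abort("no records: study_start and study_end must be given explicitly")
  }
  if (is.null(study_start)) study_start <- min(records$date)
  if (is.null(study_end)) study_end <- max(records$date)
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (study_start > study_end) rlang::abort("study_start must be <= study_end")

  # enforce one record per (date, slot): keep first, remember the rest
  key <- paste(records$date, records$slot)
  dup <- duplicated(key)
  duplicates <- records[dup, c("time", "date", "slot")]
  records <- records[!dup, , drop = FALSE]

  grid <- prompt_grid(study_start, study_end, schedule)
  out <- dplyr::left_join(grid, dplyr::select(records, -"time"),
                          by = c("date", "slot"))
  out$answered[is.na(out$answered)] <- FALSE

  # coerce value columns to their declared types; absent items become all-NA
  for (i in seq_len(nrow(questionnaire))) {
    code <- questionnaire$code[i]
    kind <- questionnaire$response_kind[i]
    col <- if (code %in% names(out)) out[[code]] else NA
    out[[code]] <- switch(kind,
      slider_0_100 = as.numeric(col),
      likert_count = as.numeric(col),
      yes_no = as.character(col),
      free_text = as.character(col))
  }
  if (!"comment" %in% names(out)) out$comment <- NA_character_
  out <- out[, c("time", "date", "slot", "answered", questionnaire$code, "comment")]

  new_esm_df(out, questionnaire, schedule, study_start, study_end, duplicates)
}

new_esm_df <- function(data, questionnaire, schedule, study_start, study_end,
                       duplicates = NULL) {
  structure(
    tibble::as_tibble(data),
    questionnaire = questionnaire,
    schedule = schedule,
    study_start = study_start,
    study_end = study_end,
    duplicates = duplicates %||% tibble::tibble(time = as.POSIXct(character(), tz = "UTC"),
                                                date = as.Date(character()),
                                                slot = factor(character())),
    class = c("esm_df", class(tibble::tibble())))
}

# all scheduled prompt times for a study window, one row per (date, slot)
prompt_grid <- function(study_start, study_end, schedule) {
  slots <- slot_names(schedule)
  days <- seq(as.Date(study_start), as.Date(study_end), by = "day")
  grid <- tidyr::expand_grid(date = days, beep = schedule$daily_times)
  grid$time <- as.POSIXct(paste(grid$date, format_clock(grid$beep)), tz = "UTC")
  grid$slot <- factor(slots[match(grid$beep, schedule$daily_times)], levels = slots)
  dplyr::arrange(dplyr::select(grid, "time", "date", "slot"), .data$time)
}

#' Accessors for `esm_df` metadata
#'
#' @param data An `esm_df` from [esm_dataset()], [simulate_esm()] or
#'   [read_esm_csv()].
#' @return The questionnaire, schedule, or study window stored on the
#'   dataset.
#' @export
esm_questionnaire_of <- function(data) attr(data, "questionnaire")

#' @rdname esm_questionnaire_of
#' @export
esm_schedule_of <- function(data) attr(data, "schedule")

#' @rdname esm_questionnaire_of
#' @export
study_window <- function(data) c(attr(data, "study_start"), attr(data, "study_end"))

#' @export
print.esm_df <- function(x, ...) {
  w <- study_window(x)
  cat("<esm_df> ", nrow(x), " prompts (", sum(x$answered), " answered), ",
      format(w[1]), " .. ", format(w[2]), "\n", sep = "")
  NextMethod()
}

#' Validate an ESM dataset against its questionnaire
#'
#' Re-checks every data invariant and returns findings as a tibble rather
#' than raising: slider values within 0–100, likert counts integral and
#' within range, yes/no values recognized, unanswered prompts carrying no
#' values, conditional children empty whenever their parent answer does
#' not match, and duplicate submissions dropped at construction time. An
#' empty result means the dataset is clean. The input is never modified.
#'
#' @param data An `esm_df`.
#' @return A tibble with columns `time`, `item`, `rule`, `message`; zero
#'   rows when all invariants hold.
#' @export
#' @examples
#' d <- simulate_esm(simulation_config(study_end = as.Date("2017-03-07")))
#' validate_dataset(d)
validate_dataset <- function(data) {
  q <- esm_questionnaire_of(data)
  if (is.null(q)) rlang::abort("not an esm_df: no questionnaire attribute")
  findings <- list()
  add <- function(time, item, rule, message) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      time = time, item = item, rule = rule, message = message)
  }

  for (i in seq_len(nrow(q))) {
    code <- q$code[i]
    v <- data[[code]]
    present <- !is.na(v)
    kind <- q$response_kind[i]
    if (kind == "slider_0_100") {
      bad <- present & (v < 0 | v > 100)
      if (any(bad)) add(data$time[bad], code, "value_out_of_range",
                        glue::glue("value out of range [0,100]: {v[bad]}"))
    } else if (kind == "likert_count") {
      mx <- q$likert_max[i]
      bad <- present & (v < 0 | v > mx | v != round(v))
      if (any(bad)) add(data$time[bad], code, "likert_out_of_range",
                        glue::glue("likert value outside 0..{mx}: {v[bad]}"))
    } else if (kind == "yes_no") {
      bad <- present & !v %in% c("yes", "no")
      if (any(bad)) add(data$time[bad], code, "invalid_yes_no",
                        glue::glue("yes/no value not 'yes'/'no': {v[bad]}"))
    }
    # unanswered prompts must be all-missing
    bad <- present & !data$answered
    if (any(bad)) add(data$time[bad], code, "unanswered_value",
                      "value present on unanswered prompt")
    # conditional children require the parent answer
    parent <- q$conditional_on[i]
    if (!is.na(parent)) {
      need <- q$conditional_value[i]
      pv <- data[[parent]]
      bad <- present & (is.na(pv) | pv != need)
      if (any(bad)) add(data$time[bad], code, "conditional_violation",
                        glue::glue("'{code}' present while '{parent}' != '{need}'"))
    }
  }

  dups <- attr(data, "duplicates")
  if (!is.null(dups) && nrow(dups)) {
    add(dups$time, NA_character_, "duplicate_prompt",
        "duplicate submission for an already-filled prompt (first kept)")
  }

  if (!length(findings)) {
    return(tibble::tibble(time = as.POSIXct(character(), tz = "UTC"),
                          item = character(), rule = character(),
                          message = character()))
  }
  dplyr::arrange(dplyr::bind_rows(findings), .data$time)
}
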