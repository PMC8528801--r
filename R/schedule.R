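#' Fixed daily prompt schedule
#'
#' ESM prompts are sent at fixed clock times each day. The defaults follow
#' a three-beep protocol: questionnaires sent at 09:00, 15:00 and 21:00,
#' to be filled out within 15 minutes of the notification, with a reminder
#' after 30 minutes and link deactivation after 60 minutes.
#'
#' @param daily_times Character `"HH:MM"` clock times, strictly increasing
#'   within the day.
#' @param instruction_window_min Minutes the participant is asked to
#'   respond within.
#' @param reminder_offset_min Minutes after the beep at which a reminder is
#'   sent.
#' @param expiry_offset_min Minutes after the beep at which the link is
#'   deactivated.
#'
#' @return A list of class `prompt_schedule` with `daily_times` stored as
#'   minutes since midnight.
#' @export
#' @examples
#' prompt_schedule()
prompt_schedule <- function(daily_times = c("09:00", "15:00", "21:00"),
                            instruction_window_min = 15,
                            reminder_offset_min = 30,
                            expiry_offset_min = 60) {
  mins <- parse_clock(daily_times)
  if (length(mins) < 1) rlang::abort("daily_times must be non-empty")
  if (any(diff(mins) <= 0)) rlang::abort("daily_times must be strictly increasing")
  if (!(instruction_window_min > 0 &&
        instruction_window_min <= reminder_offset_min &&
        reminder_offset_min < expiry_offset_min)) {
    rlang::abort("need 0 < instruction_window_min <= reminder_offset_min < expiry_offset_min")
  }
  structure(
    list(daily_times = mins,
         instruction_window_min = instruction_window_min,
         reminder_offset_min = reminder_offset_min,
         expiry_offset_min = expiry_offset_min),
    class = "prompt_schedule")
}

#' @export
print.prompt_schedule <- function(x, ...) {
  cat("<prompt_schedule> beeps at", paste(format_clock(x$daily_times), collapse = ", "),
      "| respond within", x$instruction_window_min, "min, reminder after",
      x$reminder_offset_min, "min, expiry after", x$expiry_offset_min, "min\n")
  invisible(x)
}

parse_clock <- function(x) {
  m <- stringr::str_match(x, "^(\\d{1,2}):(\\d{2})$")
  if (anyNA(m[, 1])) {
    rlang::abort(glue::glue("invalid clock time(s): {paste(x[is.na(m[, 1])], collapse = ', ')}"))
  }
  as.integer(m[, 2]) * 60L + as.integer(m[, 3])
}

format_clock <- function(mins) {
  sprintf("%02d:%02d", mins %/% 60L, mins %% 60L)
}

slot_names <- function(schedule) {
  if (length(schedule$daily_times) != 3) {
    rlang::abort("week-grid layout assumes exactly 3 daily prompts (morning/afternoon/evening)")
  }
  c("morning", "afternoon", "evening")
}

#' Map timestamps to prompt slots
#'
#' Assigns each timestamp to the slot (morning / afternoon / evening) of
#' the nearest scheduled daily time; ties go to the earlier slot. Layouts
#' downstream (week grids, movie frames) assume the three-slot protocol, so
#' schedules with a different number of daily times are rejected.
#'
#' @param time A `POSIXct` vector (or anything `as.POSIXct()` accepts).
#' @param schedule A [prompt_schedule()] with exactly 3 daily times.
#' @return A factor with levels `morning`, `afternoon`, `evening`.
#' @export
#' @examples
#' slot_of(as.POSIXct("2017-03-01 09:07", tz = "UTC"))
slot_of <- function(time, schedule = prompt_schedule()) {
  slots <- slot_names(schedule)
  time <- as.POSIXct(time, tz = "UTC")
  lt <- as.POSIXlt(time, tz = "UTC")
  mod <- lt$hour * 60 + lt$min + lt$sec / 60
  d <- abs(outer(mod, schedule$daily_times, `-`))
  # ties (equal distance to two beeps) resolve to the earlier slot
  idx <- apply(d, 1, which.min)
  factor(slots[idx], levels = slots)
}
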