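#' Define a single questionnaire item
#'
#' An item is one question of the ESM questionnaire: a short code used in
#' data files and figures, a display label, a polarity (whether high scores
#' are resilience-related "positive", symptom-related "negative", neutral
#' context, or an event question), and a response kind.
#'
#' @param code Short unique identifier, e.g. `"Alon"` or `"Appo"`.
#' @param label Display text shown in legends and reports.
#' @param polarity One of `"positive"`, `"negative"`, `"neutral"`, `"event"`.
#' @param response_kind One of `"slider_0_100"` (continuous slider, scored
#'   0–100), `"yes_no"`, `"likert_count"` (integer 0..`likert_max`), or
#'   `"free_text"`.
#' @param likert_max Maximum count for `likert_count` items; must be given
#'   for that kind and absent otherwise.
#' @param assessment_window `"momentary"` (about the current moment) or
#'   `"since_last"` (about the interval since the previous prompt).
#' @param conditional_on Optional parent item code: the item is only asked
#'   when the parent was answered with `conditional_value`.
#' @param conditional_value Required parent answer (e.g. `"yes"`).
#'
#' @return A one-row tibble describing the item.
#' @export
esm_item <- function(code, label, polarity, response_kind,
                     likert_max = NA_integer_,
                     assessment_window = "momentary",
                     conditional_on = NA_character_,
                     conditional_value = NA_character_) {
  polarity <- rlang::arg_match(polarity, c("positive", "negative", "neutral", "event"))
  response_kind <- rlang::arg_match(
    response_kind, c("slider_0_100", "yes_no", "likert_count", "free_text"))
  assessment_window <- rlang::arg_match(assessment_window, c("momentary", "since_last"))
  if (response_kind == "likert_count" && is.na(likert_max)) {
    rlang::abort(glue::glue("item '{code}': likert_count requires likert_max"))
  }
  if (response_kind != "likert_count" && !is.na(likert_max)) {
    rlang::abort(glue::glue("item '{code}': likert_max only allowed for likert_count"))
  }
  if (!is.na(conditional_on) && is.na(conditional_value)) {
    rlang::abort(glue::glue("item '{code}': conditional_on requires conditional_value"))
  }
  tibble::tibble(
    code = as.character(code), label = as.character(label),
    polarity = polarity, response_kind = response_kind,
    likert_max = as.integer(likert_max),
    assessment_window = assessment_window,
    conditional_on = as.character(conditional_on),
    conditional_value = as.character(conditional_value)
  )
}

#' Assemble items into a questionnaire
#'
#' @param items A tibble of item rows (ordered; order defines display and
#'   circle-glyph order), typically built by binding [esm_item()] rows.
#'
#' @return A tibble of class `esm_questionnaire`.
#' @export
esm_questionnaire <- function(items) {
  items <- tibble::as_tibble(items)
  if (anyDuplicated(items$code)) {
    dup <- unique(items$code[duplicated(items$code)])
    rlang::abort(glue::glue("duplicate item codes: {paste(dup, collapse = ', ')}"))
  }
  for (i in seq_len(nrow(items))) {
    parent <- items$conditional_on[i]
    if (!is.na(parent)) {
      j <- match(parent, items$code)
      if (is.na(j)) {
        rlang::abort(glue::glue(
          "item '{items$code[i]}': conditional_on refers to unknown item '{parent}'"))
      }
      if (j >= i) {
        rlang::abort(glue::glue(
          "item '{items$code[i]}': conditional parent '{parent}' must appear earlier"))
      }
    }
  }
  structure(items, class = c("esm_questionnaire", class(tibble::tibble())))
}

#' @export
print.esm_questionnaire <- function(x, ...) {
  cat("<esm_questionnaire> ", nrow(x), " items (",
      sum(x$polarity == "positive"), " positive, ",
      sum(x$polarity == "negative"), " negative)\n", sep = "")
  NextMethod()
}

#' The packaged default ESM questionnaire
#'
#' Returns the 23-item single-subject questionnaire the package ships with:
#' momentary mood/symptom sliders scored 0–100, context yes/no questions,
#' one 0–4 contact count, retrospective since-last items including
#' conditional sleep quality, and (un)pleasant event questions with
#' intensity sliders conditional on an event gate. Negative (symptom)
#' items: afraid to lose control, sadness, intrusions, afraid of being
#' alone, thought of contacting someone, inclination to cancel, cancelled
#' appointments, laid in bed, avoided everyday things. Positive
#' (resilience) items: self-encouragement, feel like doing something fun,
#' "I can do this", safe contact count, sleep quality, left the house,
#' eating, useful activities, enjoyed activities.
#'
#' @param polarity Optional named character vector overriding the default
#'   polarity of individual items, e.g. `c(Bed = "neutral")`.
#' @return An [esm_questionnaire()].
#' @export
#' @examples
#' q <- default_questionnaire()
#' table(q$polarity)
default_questionnaire <- function(polarity = NULL) {
  items <- dplyr::bind_rows(
    esm_item("Ctrl",  "I am afraid to lose control", "negative", "slider_0_100"),
    esm_item("Sad",   "I feel sad / useless / meaningless", "negative", "slider_0_100"),
    esm_item("Intr",  "How convincing are the intrusions", "negative", "slider_0_100"),
    esm_item("Enco",  "I can encourage myself", "positive", "slider_0_100"),
    esm_item("Fun",   "I feel like doing something fun", "positive", "slider_0_100"),
    esm_item("Cando", "I have the feeling that 'I can do this'", "positive", "slider_0_100"),
    esm_item("Comp",  "Are you in company?", "neutral", "yes_no"),
    esm_item("Alon",  "How afraid are you of being alone?", "negative", "slider_0_100"),
    esm_item("Cont",  "How often have you been in contact with someone you feel safe with?",
             "positive", "likert_count", likert_max = 4L, assessment_window = "since_last"),
    esm_item("Thco",  "How often have you thought of contacting someone you feel safe with?",
             "negative", "slider_0_100", assessment_window = "since_last"),
    esm_item("Appo",  "How strong was your inclination to cancel appointments?",
             "negative", "slider_0_100", assessment_window = "since_last"),
    esm_item("Canc",  "Have you actually cancelled appointments?",
             "negative", "yes_no", assessment_window = "since_last"),
    esm_item("Bed",   "Have you laid on the couch or in bed?",
             "negative", "slider_0_100", assessment_window = "since_last"),
    esm_item("Slept", "Have you slept since the last measurement point?",
             "neutral", "yes_no", assessment_window = "since_last"),
    esm_item("Sleep", "How did you sleep?",
             "positive", "slider_0_100", assessment_window = "since_last",
             conditional_on = "Slept", conditional_value = "yes"),
    esm_item("Out",   "Did you leave the house?",
             "positive", "slider_0_100", assessment_window = "since_last"),
    esm_item("Eat",   "How did you eat?",
             "positive", "slider_0_100", assessment_window = "since_last"),
    esm_item("Avoid", "Have you avoided everyday things?",
             "negative", "slider_0_100", assessment_window = "since_last"),
    esm_item("Usef",  "Have you done useful (important) things?",
             "positive", "slider_0_100", assessment_window = "since_last"),
    esm_item("Enjoy", "Have you enjoyed your activities?",
             "positive", "slider_0_100", assessment_window = "since_last"),
    esm_item("Event", "Have you experienced any (un)pleasant everyday occurrences?",
             "event", "yes_no", assessment_window = "since_last"),
    esm_item("Pleas", "How pleasant was this experience?",
             "event", "slider_0_100", assessment_window = "since_last",
             conditional_on = "Event", conditional_value = "yes"),
    esm_item("Unpl",  "How unpleasant was this experience?",
             "event", "slider_0_100", assessment_window = "since_last",
             conditional_on = "Event", conditional_value = "yes")
  )
  if (!is.null(polarity)) {
    bad <- setdiff(names(polarity), items$code)
    if (length(bad)) rlang::abort(glue::glue("unknown item codes in polarity override: {paste(bad, collapse = ', ')}"))
    items$polarity[match(names(polarity), items$code)] <- unname(polarity)
  }
  esm_questionnaire(items)
}

#' Item codes of a given polarity
#'
#' @param questionnaire An [esm_questionnaire()].
#' @param polarity Polarity group to select.
#' @param kinds Response kinds to keep (default all).
#' @return Character vector of item codes, in questionnaire order.
#' @export
polarity_codes <- function(questionnaire, polarity,
                           kinds = c("slider_0_100", "yes_no", "likert_count", "free_text")) {
  questionnaire$code[questionnaire$polarity %in% polarity &
                       questionnaire$response_kind %in% kinds]
}

# Slider items whose 0-100 value is drawn on the glyph ring: unconditional
# positive/negative sliders. Conditional sliders (sleep quality, event
# intensities) are displayed as shaded centre badges instead.
ring_codes <- function(questionnaire) {
  q <- questionnaire
  q$code[q$response_kind == "slider_0_100" &
           q$polarity %in% c("positive", "negative") &
           is.na(q$conditional_on)]
}

#' Write / read a questionnaire schema config
#'
#' Serializes a questionnaire (and optionally a prompt schedule) to a YAML
#' config with one block per item (code/label/polarity/kind/conditional
#' fields) and a `schedule` block with `"HH:MM"` daily times.
#'
#' @param questionnaire An [esm_questionnaire()].
#' @param path File path for the YAML config.
#' @param schedule Optional [prompt_schedule()] stored alongside the items.
#' @return `write_questionnaire()` returns `path` invisibly;
#'   `read_questionnaire()` returns a list with elements `questionnaire`
#'   and `schedule` (the latter `NULL` when the file has no schedule block).
#' @export
write_questionnaire <- function(questionnaire, path, schedule = NULL) {
  items <- purrr::pmap(questionnaire, function(code, label, polarity, response_kind,
                                               likert_max, assessment_window,
                                               conditional_on, conditional_value) {
    it <- list(code = code, label = label, polarity = polarity,
               response_kind = response_kind, assessment_window = assessment_window)
    if (!is.na(likert_max)) it$likert_max <- likert_max
    if (!is.na(conditional_on)) {
      it$conditional_on <- conditional_on
      it$conditional_value <- conditional_value
    }
    it
  })
  cfg <- list(items = items)
  if (!is.null(schedule)) {
    cfg$schedule <- list(
      daily_times = format_clock(schedule$daily_times),
      instruction_window_min = schedule$instruction_window_min,
      reminder_offset_min = schedule$reminder_offset_min,
      expiry_offset_min = schedule$expiry_offset_min
    )
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_questionnaire
#' @export
read_questionnaire <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$items)) rlang::abort("schema config has no 'items' block")
  items <- dplyr::bind_rows(purrr::map(cfg$items, function(it) {
    esm_item(
      code = it$code, label = it$label, polarity = it$polarity,
      response_kind = it$response_kind,
      likert_max = it$likert_max %||% NA_integer_,
      assessment_window = it$assessment_window %||% "momentary",
      conditional_on = it$conditional_on %||% NA_character_,
      conditional_value = it$conditional_value %||% NA_character_
    )
  }))
  sched <- NULL
  if (!is.null(cfg$schedule)) {
    s <- cfg$schedule
    sched <- prompt_schedule(
      daily_times = s$daily_times,
      instruction_window_min = s$instruction_window_min %||% 15,
      reminder_offset_min = s$reminder_offset_min %||% 30,
      expiry_offset_min = s$expiry_offset_min %||% 60
    )
  }
  list(questionnaire = esm_questionnaire(items), schedule = sched)
}
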