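# small questionnaire and datasets used across the io / schema tests

mini_questionnaire <- function() {
  esm_questionnaire(dplyr::bind_rows(
    esm_item("NegA", "worry", "negative", "slider_0_100"),
    esm_item("NegB", "sadness", "negative", "slider_0_100"),
    esm_item("PosA", "confidence", "positive", "slider_0_100"),
    esm_item("Comp", "in company?", "neutral", "yes_no"),
    esm_item("Slp", "slept?", "neutral", "yes_no", assessment_window = "since_last"),
    esm_item("SlpQ", "sleep quality", "positive", "slider_0_100",
             assessment_window = "since_last",
             conditional_on = "Slp", conditional_value = "yes"),
    esm_item("Cnt", "safe contacts", "positive", "likert_count", likert_max = 4L,
             assessment_window = "since_last")))
}

# two fully answered days (6 prompts) for the mini questionnaire
mini_records <- function() {
  times <- generate_prompt_times(as.Date("2017-03-01"), as.Date("2017-03-02"))
  tibble::tibble(
    time = times,
    NegA = c(10, 20, 30, 40, 50, 60),
    NegB = c(15, 25, 35, 45, 55, 65),
    PosA = c(90, 80, 70, 60, 50, 40),
    Comp = c("yes", "no", "yes", "no", "yes", "no"),
    Slp = c("yes", "no", "no", "yes", "no", "no"),
    SlpQ = c(70, NA, NA, 55, NA, NA),
    Cnt = c(0, 1, 2, 3, 4, 2),
    comment = c("fine morning", NA, NA, "with friends, coffee", NA, NA))
}

mini_dataset <- function() {
  esm_dataset(mini_records(), mini_questionnaire())
}

short_sim <- function(seed = 1, end = "2017-03-28", ...) {
  simulate_esm(simulation_config(study_end = as.Date(end), seed = seed, ...))
}

mini_dataset_with_violation <- function() {
  rec <- mini_records()
  rec$NegA[2] <- 150
  esm_dataset(rec, mini_questionnaire())
}

mini_schema_file <- function(dir) {
  path <- file.path(dir, "schema.yaml")
  write_questionnaire(mini_questionnaire(), path, schedule = prompt_schedule())
  path
}

monday_of_for_test <- function(d) d - (as.integer(format(d, "%u")) - 1L)

# ring items restated independently of the implementation helper
ring_codes_for_test <- function(q) {
  q$code[q$response_kind == "slider_0_100" &
           q$polarity %in% c("positive", "negative") &
           is.na(q$conditional_on)]
}
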