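#' Specify a relapse episode for the simulator
#'
#' During an episode the latent means of negative (symptom) items are
#' raised and those of positive (resilience) items lowered, with a linear
#' ramp of `ramp_days` at onset and offset so the shift builds up and ebbs
#' away gradually rather than switching on.
#'
#' @param start_date,end_date Episode window (`Date`), `start < end`.
#' @param negative_shift Units (0–100 scale) added to negative-item means.
#' @param positive_shift Units subtracted from positive-item means.
#' @param ramp_days Length of the linear onset/offset ramps, in days.
#' @return A one-row tibble.
#' @export
episode_spec <- function(start_date, end_date, negative_shift = 30,
                         positive_shift = 20, ramp_days = 7) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (!(start_date < end_date)) rlang::abort("episode needs start_date < end_date")
  if (negative_shift < 0 || positive_shift < 0 || ramp_days < 0) {
    rlang::abort("episode shifts and ramp_days must be >= 0")
  }
  tibble::tibble(start_date = start_date, end_date = end_date,
                 negative_shift = negative_shift, positive_shift = positive_shift,
                 ramp_days = ramp_days)
}

default_item_means <- function() c(
  Ctrl = 30, Sad = 35, Intr = 30, Enco = 55, Fun = 45, Cando = 50,
  Comp = 55, Alon = 25, Cont = 45, Thco = 30, Appo = 35, Canc = 20,
  Bed = 30, Slept = 80, Sleep = 60, Out = 50, Eat = 55, Avoid = 15,
  Usef = 45, Enjoy = 50)

default_comment_templates <- function() c(
  "A difficult morning, but it got better after lunch.",
  "My parents came over, that helped a lot.",
  "Felt tense about the appointment tomorrow.",
  "Quiet day at home, mostly on the couch.",
  "Proud that I finished everything I planned.",
  "Hardly slept, the intrusions kept coming back.",
  "Went for a long walk with a friend.",
  "An unexpected phone call upset me.")

#' Configure the single-subject study simulator
#'
#' The defaults emulate a 52-week, three-prompts-a-day self-monitoring
#' study starting 1 March 2017: two relapse episodes (a spring setback in
#' mid-April–mid-May and a longer autumn relapse from late September that
#' deepens into December), a two-week fully missed block in mid-May, 92%
#' compliance elsewhere, occasional (un)pleasant events, and sporadic
#' free-text comments. Per-item latent series are AR(1) on the 0–100 scale
#' with stationary standard deviation `sigma`.
#'
#' @param questionnaire An [esm_questionnaire()]; defaults to
#'   [default_questionnaire()].
#' @param schedule A [prompt_schedule()].
#' @param study_start,study_end Study window dates.
#' @param mu Named vector of per-item baseline latent means (0–100 units);
#'   names are item codes. Items missing from `mu` default to 50.
#' @param sigma Named vector or scalar of per-item latent standard
#'   deviations (0–100 units).
#' @param phi Shared AR(1) coefficient in `[0, 1)`.
#' @param episodes Tibble of [episode_spec()] rows (bind with
#'   `dplyr::bind_rows()`); may have zero rows.
#' @param compliance_prob Probability an offered prompt is answered.
#' @param block_missing Tibble with `start_date`, `end_date` columns: date
#'   windows in which no prompt is answered at all.
#' @param event_prob Probability an answered prompt reports an
#'   (un)pleasant event.
#' @param comment_prob Probability an answered prompt carries a free-text
#'   comment.
#' @param comment_templates Comment texts sampled from.
#' @param seed Integer seed; simulation is fully reproducible from it.
#' @return A list of class `esm_sim_config`.
#' @export
simulation_config <- function(questionnaire = default_questionnaire(),
                              schedule = prompt_schedule(),
                              study_start = as.Date("2017-03-01"),
                              study_end = as.Date("2018-02-27"),
                              mu = default_item_means(),
                              sigma = 15,
                              phi = 0.5,
                              episodes = dplyr::bind_rows(
                                episode_spec("2017-04-10", "2017-05-12",
                                             negative_shift = 25, positive_shift = 15,
                                             ramp_days = 5),
                                episode_spec("2017-09-20", "2017-12-24",
                                             negative_shift = 30, positive_shift = 20,
                                             ramp_days = 10)),
                              compliance_prob = 0.92,
                              block_missing = tibble::tibble(
                                start_date = as.Date("2017-05-13"),
                                end_date = as.Date("2017-05-26")),
                              event_prob = 0.15,
                              comment_prob = 0.08,
                              comment_templates = default_comment_templates(),
                              seed = 1L) {
  codes <- questionnaire$code[questionnaire$response_kind != "free_text" &
                                questionnaire$polarity != "event"]
  mu_full <- setNames(rep(50, length(codes)), codes)
  mu_full[intersect(names(mu), codes)] <- mu[intersect(names(mu), codes)]
  sd_full <- setNames(rep(sigma[1], length(codes)), codes)
  if (!is.null(names(sigma))) sd_full[intersect(names(sigma), codes)] <-
      sigma[intersect(names(sigma), codes)]
  if (any(mu_full < 0 | mu_full > 100)) rlang::abort("mu must be within [0,100]")
  if (any(sd_full < 0)) rlang::abort("sigma must be >= 0")
  if (phi < 0 || phi >= 1) rlang::abort("phi must be in [0,1)")
  probs <- c(compliance_prob, event_prob, comment_prob)
  if (any(probs < 0 | probs > 1)) rlang::abort("probabilities must be in [0,1]")
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (study_start > study_end) rlang::abort("study_start must be <= study_end")
  structure(list(
    questionnaire = questionnaire, schedule = schedule,
    study_start = study_start, study_end = study_end,
    mu = mu_full, sigma = sd_full, phi = phi, episodes = episodes,
    compliance_prob = compliance_prob, block_missing = block_missing,
    event_prob = event_prob, comment_prob = comment_prob,
    comment_templates = comment_templates, seed = as.integer(seed)),
    class = "esm_sim_config")
}

#' All scheduled prompt times of a study window
#'
#' @param study_start,study_end Study window dates (both inclusive).
#' @param schedule A [prompt_schedule()].
#' @return Sorted `POSIXct` vector, one element per (day, daily time).
#' @export
#' @examples
#' generate_prompt_times(as.Date("2017-03-01"), as.Date("2017-03-01"))
generate_prompt_times <- function(study_start, study_end,
                                  schedule = prompt_schedule()) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (study_start > study_end) rlang::abort("study_start must be <= study_end")
  days <- seq(study_start, study_end, by = "day")
  times <- as.POSIXct(outer(paste(days), format_clock(schedule$daily_times), paste),
                      tz = "UTC")
  sort(times)
}

# per-prompt episode shift multiplier in [0,1]: trapezoid with linear ramps
episode_weight <- function(dates, episode) {
  d <- as.numeric(dates)
  s <- as.numeric(episode$start_date); e <- as.numeric(episode$end_date)
  r <- max(episode$ramp_days, 1e-9)
  w <- pmin(1, pmax(0, (d - s) / r), pmax(0, (e - d) / r))
  w
}

#' Simulate a single-subject ESM dataset
#'
#' Each non-event item has a latent series `x_t = mu + shift(t) + e_t`
#' where `e_t` is AR(1) with coefficient `phi` and stationary standard
#' deviation `sigma` (innovations scaled by `sqrt(1 - phi^2)`), and
#' `shift(t)` is the trapezoidal episode shift (positive for negative
#' items, negative for positive items). Sliders observe
#' `round(clip(x, 0, 100))` — clipping produces the floor pile-up at 0
#' typical of symptom items. Yes/no items are Bernoulli draws with
#' probability `plogis((x - 50) / 12)`; count items bin the clipped latent
#' into `likert_max + 1` equal-width bins. Conditional children are only
#' generated when the parent condition holds. Event gates fire with
#' probability `event_prob`; a fired event is pleasant, unpleasant or both
#' (odds 45:45:10) with slider-like intensities. Prompts are unanswered
#' with probability `1 - compliance_prob` and always within the
#' block-missing windows.
#'
#' @param config An [simulation_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A validated `esm_df` (zero findings by construction).
#' @export
#' @examples
#' d <- simulate_esm(simulation_config(study_end = as.Date("2017-03-14"), seed = 7))
#' nrow(d)
simulate_esm <- function(config, seed = NULL) {
  if (!inherits(config, "esm_sim_config")) rlang::abort("config must be a simulation_config()")
  q <- config$questionnaire
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %||% config$seed)

  times <- generate_prompt_times(config$study_start, config$study_end, config$schedule)
  n <- length(times)
  dates <- as.Date(times, tz = "UTC")

  # trapezoidal episode shifts, shared across items within a polarity
  neg_shift <- rep(0, n); pos_shift <- rep(0, n)
  if (nrow(config$episodes)) {
    for (i in seq_len(nrow(config$episodes))) {
      ep <- config$episodes[i, ]
      w <- episode_weight(dates, ep)
      neg_shift <- neg_shift + w * ep$negative_shift
      pos_shift <- pos_shift + w * ep$positive_shift
    }
  }

  latent <- function(code) {
    mu <- config$mu[[code]]
    sd <- config$sigma[[code]]
    phi <- config$phi
    e0 <- rnorm(1, 0, sd)
    eps <- rnorm(n, 0, sd * sqrt(1 - phi^2))
    e <- as.numeric(stats::filter(eps, phi, method = "recursive", init = e0))
    pol <- q$polarity[q$code == code]
    shift <- if (pol == "negative") neg_shift else if (pol == "positive") -pos_shift else 0
    mu + shift + e
  }

  values <- tibble::tibble(time = times)
  for (i in seq_len(nrow(q))) {
    code <- q$code[i]; kind <- q$response_kind[i]
    if (q$polarity[i] == "event" || kind == "free_text") next
    x <- latent(code)
    values[[code]] <- switch(kind,
      slider_0_100 = round(pmin(100, pmax(0, x))),
      yes_no = ifelse(rbinom(n, 1, plogis((x - 50) / 12)) == 1, "yes", "no"),
      likert_count = {
        mx <- q$likert_max[i]
        pmin(mx, floor(pmin(100, pmax(0, x)) / (100 / (mx + 1))))
      })
  }

  # event gate and intensities
  ev_codes <- q$code[q$polarity == "event"]
  if (length(ev_codes)) {
    gate <- ev_codes[is.na(q$conditional_on[match(ev_codes, q$code)])][1]
    fired <- rbinom(n, 1, config$event_prob) == 1
    values[[gate]] <- ifelse(fired, "yes", "no")
    kids <- ev_codes[!is.na(q$conditional_on[match(ev_codes, q$code)])]
    kind_draw <- sample(c("first", "second", "both"), n, replace = TRUE,
                        prob = c(0.45, 0.45, 0.10))
    for (k in seq_along(kids)) {
      on <- fired & (kind_draw == "both" |
                       kind_draw == c("first", "second")[pmin(k, 2)])
      intensity <- round(pmin(100, pmax(0, rnorm(n, 55, 20))))
      values[[kids[k]]] <- ifelse(on, intensity, NA_real_)
    }
  }

  # blank conditional children whose parent condition fails
  for (i in seq_len(nrow(q))) {
    parent <- q$conditional_on[i]
    if (is.na(parent) || q$polarity[i] == "event") next
    ok <- !is.na(values[[parent]]) & values[[parent]] == q$conditional_value[i]
    values[[q$code[i]]][!ok] <- NA
  }

  # compliance: missed prompts and block-missing windows
  answered <- runif(n) < config$compliance_prob
  if (nrow(config$block_missing)) {
    for (i in seq_len(nrow(config$block_missing))) {
      b <- config$block_missing[i, ]
      answered[dates >= b$start_date & dates <= b$end_date] <- FALSE
    }
  }
  values$answered <- answered

  # free-text comments on a fraction of answered prompts
  with_comment <- answered & runif(n) < config$comment_prob
  values$comment <- NA_character_
  if (any(with_comment) && length(config$comment_templates)) {
    values$comment[with_comment] <- sample(config$comment_templates,
                                           sum(with_comment), replace = TRUE)
  }

  for (code in q$code) {
    if (code %in% names(values)) values[[code]][!answered] <- NA
  }

  esm_dataset(values, q, config$schedule,
              study_start = config$study_start, study_end = config$study_end)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
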