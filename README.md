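# esmviz

Visual feedback for single-subject experience-sampling (ESM) data.

In experience-sampling studies a person answers a short questionnaire
several times a day — here three fixed beeps at 09:00, 15:00 and 21:00 —
for weeks or months, producing an intensive longitudinal record of
momentary mood, symptoms, context and daily events. Feedback built from
summary statistics alone hides the dynamics in such data. `esmviz` gives
the raw data back as pictures: boxplot overviews, smoothed two-panel
timelines, a *circle figure* that shows every answer of one prompt at
once, week-by-week grids of circle figures, an all-responses poster, a
per-week "movie" pairing the macro timeline with the micro week grid,
and a self-contained interactive HTML report. It is aimed at researchers
and clinicians who want descriptive, interpretable feedback for a single
participant — for example a patient self-monitoring around relapse.

## What it computes

* **Data model.** A typed questionnaire (`default_questionnaire()` ships
  a 23-item schema: 0–100 sliders with positive/negative polarity, yes/no
  context items, a 0–4 contact count, conditional sleep-quality and event
  questions) plus a prompt schedule (3 beeps/day, 15-min instruction
  window, 30-min reminder, 60-min link expiry). Datasets are tibbles with
  one row per scheduled prompt; unanswered prompts are explicit rows, so
  missingness is first-class.
* **Boxplot summaries.** Per item: median, quartiles by linear
  interpolation of order statistics, whiskers to the most extreme points
  within 1.5 × IQR of the hinges, the rest as outliers; panels ordered on
  median within polarity.
* **LOESS smoothing.** Classical locally weighted regression: at each
  grid time a degree-1 weighted least-squares fit over the
  `ceiling(bandwidth × n)` nearest points with tricube weights
  `w = (1 − (d/d_max)³)³`, no robustness iterations, default bandwidth
  0.2.
* **Episode flagging.** The negative-item composite is smoothed and
  maximal windows above `median + k·1.4826·MAD` lasting ≥ `min_days` are
  flagged — a descriptive screen for relapse-like setbacks.
* **Simulator.** `simulate_esm()` generates a full synthetic study —
  AR(1) latent series per item, trapezoidal relapse episodes, compliance
  gaps and a block-missing fortnight, events and comments — fully
  reproducible from a seed, so the whole pipeline is testable without
  patient data.

## Worked example

```r
library(esmviz)

d <- simulate_esm(simulation_config(seed = 42))
d
#> <esm_df> 1092 prompts (958 answered), 2017-03-01 .. 2018-02-27

nrow(validate_dataset(d))
#> [1] 0

tidy(item_summaries(d))[1:3, c("item", "polarity", "n", "median", "q1", "q3")]
#> # A tibble: 3 × 6
#>   item  polarity     n median    q1    q3
#> 1 Ctrl  negative   958   38      25    51
#> 2 Sad   negative   958   44      31    58
#> 3 Intr  negative   958   37.5    24    52

tidy(flag_episodes(d))
#> # A tibble: 2 × 4
#>   start      end        n_prompts  peak
#> 1 2017-04-23 2017-04-30        20  45.2
#> 2 2017-09-26 2017-12-16       223  58.3

glance(missingness_summary(d))
#> # A tibble: 1 × 4
#>   n_prompts n_gaps longest_gap_prompts mean_item_missing
#> 1      1092     86                  42             0.196
```

The simulated year has 1092 scheduled prompts (3 × 364 days) of which 958
were answered; the longest run of missed prompts is the planted two-week
block in mid-May (42 prompts). The two flagged windows recover the two
planted relapse episodes: a short spring setback in late April and the
long autumn relapse running into December. From here,
`plot_boxplots(d)`, `plot_timeline(d)`, `render_circle()`,
`render_week_grid()`, `make_poster()`, `esm_movie()` and `build_report()`
turn the same dataset into the feedback figures; see the vignette
`vignettes/esm-visual-feedback.Rmd` for the methods behind each.

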