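---
title: "Methods: visual feedback for single-subject ESM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visual feedback for single-subject ESM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmviz)
```

## The setting

Experience-sampling (ESM) studies ask a participant to rate momentary
mood, symptoms and context several times a day over weeks to months.
`esmviz` targets the single-subject case: a fixed questionnaire delivered
at fixed clock times (default 09:00, 15:00, 21:00, with a 15-minute
instruction window, a reminder after 30 minutes, and link deactivation
after 60 minutes), producing one record per `(date, slot)` prompt. The
package's job is descriptive: turn that raw record — including its
missingness, its free-text comments, and its occasional events — into
figures a participant and clinician can read together. It deliberately
fits no dynamic model; vector-autoregressive or network feedback is out
of scope.

## The data model

A questionnaire is an ordered tibble of items. Each item has a short
code, a display label, a *polarity* — `negative` for symptom-related
items, `positive` for resilience-related items, `neutral` for context,
`event` for occurrence questions — and a response kind: a 0–100 slider,
yes/no, a bounded count (`likert_count`, here 0–4 for safe contacts), or
free text. Items may be conditional on a parent answer (sleep quality is
only asked after sleeping; event intensities only after an event).
Polarity drives everything downstream (colours, panel assignment,
composites), and because a sensible assignment is ultimately a clinical
judgement, the packaged defaults can be overridden per item
(`default_questionnaire(polarity = c(Bed = "neutral"))`) or replaced
wholesale via a YAML schema (`read_questionnaire()`).

Datasets are wide tibbles with one row per *scheduled* prompt.
Materializing unanswered prompts as `answered = FALSE` rows is a design
commitment: missingness is data, not absence of data. `NA` ("not filled
in") is kept distinct from a recorded `0` or `"no"` throughout the model,
even though the classic circle-figure rendering deliberately maps both to
grey (see below). Timestamps are timezone-naive nominal clock times
stored as UTC; a 21:00 beep is 21:00 regardless of daylight-saving
transitions, which is how delivery systems schedule prompts. Weeks are
ISO weeks starting Monday. Duplicate submissions for one prompt keep the
first record (delivery links expire, so later rows are anomalies) and
surface as validation findings rather than silent drops.

`validate_dataset()` re-checks every invariant — slider range, count
range and integrality, yes/no vocabulary, all-missing unanswered rows,
conditional children without their parent answer — and returns findings
as a tibble instead of raising, so a pipeline can triage real-world files.
Structural problems (columns that are not item codes, unparseable
timestamps) do raise, naming the offender.

## The simulator

Real single-subject clinical data cannot ship with a package, so the
simulator is a first-class module: every figure and statistic here is
exercised against synthetic studies whose ground truth is known. The
default configuration emulates a 52-week study (2017-03-01 to
2018-02-27, 1092 prompts) with two relapse episodes — a spring setback
(10 Apr – 12 May, negative shift +25, positive −15, 5-day ramps) and a
longer autumn relapse (20 Sep – 24 Dec, +30/−20, 10-day ramps) — a
completely missed fortnight (13–26 May), 92% compliance elsewhere,
events on 15% of answered prompts and comments on 8%.

Each non-event item follows a latent series
`x_t = mu_i + shift(t) + e_t`, with `e_t` AR(1):
`e_t = phi * e_{t-1} + eps_t`, `eps_t ~ N(0, sigma_i * sqrt(1 - phi^2))`,
so the stationary standard deviation is exactly `sigma_i` whatever
`phi`. AR(1) is the minimal structure that produces the smooth
multi-week drifts visible in real affect series; `phi = 0.5` gives
between-prompt correlation without long excursions. Sliders observe
`round(clip(x, 0, 100))` — clipping then rounding, rather than
truncated-normal sampling, because the boundary pile-up at 0 it produces
matches the floor effects typical of symptom items. Yes/no items draw
from `plogis((x - 50) / 12)`; counts bin the clipped latent into
`likert_max + 1` equal-width bins. Episode shifts are trapezoidal
(linear onset/offset ramps) because relapses build and ebb rather than
switch. Baseline means default to low-ish negative items (15–35) and
mid-range positive items (45–60) with `sigma = 15`; these are chosen to
be qualitatively realistic (scores rarely above 80, frequent floor
contact) and are not claims about any real patient.

What the simulator does **not** emulate: cross-item dependence beyond the
shared episode shift (no cross-lagged structure), time-of-day cycles,
reactivity or compliance decay, and any coupling between events and mood.
Tests passing on this generator therefore demonstrate correctness of the
pipeline and recoverability of regime-scale signal — not that the
detector is calibrated for any particular patient population.

## Descriptive statistics

**Boxplot summaries.** Quartiles use linear interpolation between order
statistics (`stats::quantile` type 7, the common statistical-software
default; no convention is canonical and this one is reproducible
everywhere). Whiskers run to the most extreme data points within
1.5 × IQR of the hinges; points beyond are outliers. One degenerate case
needs a rule: with interpolated quartiles and a tiny sample whose every
point beyond a hinge is an outlier, "whiskers are data points" and
"whiskers enclose the box" cannot both hold; the whisker then collapses
onto the hinge. Items not asked at every prompt (events, counts) are
excluded from boxplot panels; panels order items by median within each
polarity group, ascending by default (`direction = "desc"` flips it, as
the convention is a display choice), ties broken alphabetically so the
ordering is total and stable.

**Smoothing.** `loess_smooth()` is the classical definition, implemented
directly because its exact form is the package's contract: for each grid
time, take the `q = ceiling(bandwidth * n)` nearest observations by time
distance (measured in days, so same-day prompts are 0.25 days apart),
weight them by tricube `(1 - (d/d_max)^3)^3`, fit a degree-1 weighted
least squares, evaluate at the grid time; no robustness iterations.
Degenerate windows fall back to the weighted mean (zero time spread) or
the plain mean (all points at the grid instant). The default bandwidth
is 0.2 — deliberately low, but any smoother can hide sudden jumps, so
the timeline exposes `bandwidth` and a raw-data overlay rather than
fixing either; varying both is part of reading the figure. The test
suite holds the implementation to a pointwise `lm.wfit` oracle at 1e−9
relative tolerance and to exact reproduction of linear data.

**Composites and episode flagging.** The negative composite is the
per-prompt mean of available negative sliders (missing if none).
`flag_episodes()` smooths it (bandwidth 0.2), then flags maximal windows
above `median + k_sd * 1.4826 * MAD` lasting at least `min_days` days.
Median/MAD rather than mean/SD because the episodes themselves would
inflate a non-robust scale estimate. Defaults `k_sd = 2`, `min_days = 7`
were fixed at design time: 2 robust SDs separates regime shifts from
smoothed noise, and a week is the shortest clinically meaningful
setback at three prompts a day. This is a descriptive screen to direct
visual attention, not a change-point model, and its guarantees are
stated only under the simulator's conditions (the acceptance suite runs
50 seeded studies with two 3-sigma episodes and requires precision and
recall ≥ 0.9).

## The figures

**Circle figure.** One prompt, all answers at once. Unconditional
positive/negative sliders are ring nodes: the negative arc fills the
left half and the positive arc the right, both starting at 12 o'clock,
evenly spaced in questionnaire order (the exact placement is a
convention; questionnaire order keeps it stable across figures). A
node's fill rises linearly with the score — empty grey at 0, completely
filled at 100. Everything else is a centre badge: sleep ("S", shaded
green by sleep quality), company, cancelled appointments (a square "c"),
the safe-contact count digit, pleasant/unpleasant events shaded by
intensity, and a comment marker; comments render as an adjacent text
box. Conditional sliders thus appear as badge *shades*, not ring nodes —
that is what makes the two-step questions (slept? how well?) legible at
a glance. By default a grey node is ambiguous between "scored zero" and
"did not fill in", with the legend carrying that caveat, exactly because
the classic rendering made that choice; since the data model preserves
the distinction, `distinguish_missing = TRUE` adds a tick to missing
nodes instead. Unanswered prompts get an explicit dashed "no response"
placeholder rather than an all-grey circle, which would otherwise be
indistinguishable from an all-zero answer inside a week grid.

**Week grid, poster, timeline.** The week grid is 3 slot rows × 7
weekday columns (Monday start); cells outside the study window stay
blank. The poster stacks all study weeks chronologically (4 per A3 page
by default); week backgrounds can optionally be tinted from blue to pink
by the weekly negative composite — the tint is computed, never asserted,
and off by default since the glyph colours already carry the signal. The
timeline is two panels (negative left, positive right) of per-item
smoothed curves with rug ticks for unanswered prompts and an optional
translucent blue overlay on a highlighted window.

**Movie and report.** `build_week_frames()` plans one frame per ISO week
intersecting the study window; each rendered frame pairs the full-study
timeline (overlay on that week) with that week's grid. Frames encode to
animated GIF at 1 frame per second by default (playback speed is taste;
`fps` is exposed). The GIF writer is a minimal self-contained GIF89a
encoder: frames quantized to a fixed 6×6×6 colour cube and emitted as
fixed-width 9-bit LZW literal codes with periodic clear codes — larger
files than a true compressor, but deterministic and dependency-free;
MP4 output is not provided. The interactive report is one
self-contained HTML file (no server, no network assets): the timeline as
inline SVG with per-item toggles, raw-overlay and comment toggles, a
date-range zoom, and every week grid embedded as an inline PNG. The
numbers behind the report's curves are the `smooth_items()` output,
embedded verbatim as JSON, and the test suite asserts that equivalence.

## Rendering determinism

Figures are drawn with fixed geometry, fonts and device settings and no
randomness, so rendering the same spec twice yields byte-identical PNGs;
the tests rely on this instead of stored golden images. Glyph geometry
(angles, fill fractions) lives in the spec, not the device, so it is
resolution-independent by construction.

## Problem sizes in the test suite

The suite simulates short studies (2–6 weeks) for structural and
round-trip checks, one 52-week study for week/frame arithmetic, 1000
random samples for the boxplot oracle, and 50 full-year studies for
episode precision/recall; the whole run takes on the order of two
minutes on one CPU. These sizes were chosen as the smallest that
exercise every code path and give stable Monte-Carlo estimates.

## Limitations

Single subject only; fixed-time schedules with exactly three daily
prompts for the grid/movie layouts (other schedules pass through the
data model but have no week-grid rendering); no inferential statistics;
polarity assignment is an input, not an inference; and the simulator's
realism bounds what green tests can claim about clinical data. For a new
questionnaire the schema config, polarity assignment and badge mapping
need review before the figures mean what they appear to mean.
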