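---
title: "Simulating SpO2 alarm strategies under automated FiO2 control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating SpO2 alarm strategies under automated FiO2 control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxialarm)
```

## The problem

Neonates on respiratory support are monitored by pulse oximetry, and the
SpO2 alarm is both the most frequent and the most frequently ignored alarm
in the NICU. When inspired oxygen is titrated by a closed-loop controller
(Auto-FiO2), the controller — not the nurse — handles routine excursions,
so the alarm's job changes: it should flag only the episodes the automation
cannot resolve. That motivates comparing a *tight* alarm strategy
(thresholds just outside the SpO2 target range, short persistence delay)
with a *loose* one (thresholds 2% wider, a three-times-longer delay) in a
randomized crossover design, with alarm frequency as the effectiveness
outcome and time at SpO2 extremes as the safety outcome.

Patient-level monitoring logs from such studies are not publicly deposited,
so this package pairs the full analysis pipeline with a synthetic-data
generator that reproduces the *statistical structure* of 5-second
SpO2/FiO2 logs under closed-loop control. Everything downstream of the
generator — alarm detection, exposure metrics, paired statistics — is
exactly the computation one would run on real device exports in the same
CSV layout.

## The synthetic signal model

`generate_subject()` builds each subject-day from four components, all
deterministic given `(seed, subject_index)`:

* **Baseline + controller pull-back.** SpO2 sits at the target-range
  midpoint (91.5% for the default 88–95% range) plus AR(1) noise. The
  lag-1 coefficient is `exp(-5 / controller_timeconstant)`, so the noise's
  mean reversion *is* the emulated controller's pull toward range; the
  stationary SD (`noise_sd`, default 1.5%) sets the width of the unimodal
  in-range histogram that emerges. This first-order relaxation is
  explicitly **not** the proprietary control algorithm used on real
  ventilators — it is a stand-in with the right qualitative behavior.
* **Desaturation events.** Poisson arrivals (`desat_rate`, default 5/h)
  with half-sine deflections whose peak depth is `desat_depth` ± 3 below
  the range floor. Durations follow a log-normal body (median 30 s,
  `sdlog` 0.6) truncated at 60 s, plus an exponential tail (mean excess
  90 s) entered with probability `tail_frac = 0.03` — so most events are
  shorter than a minute and prolonged hypoxemia (> 1 min below 80%) occurs
  on the order of once per day, matching the descriptive magnitudes
  reported for infants managed this way (a few desaturations per hour,
  hypoxemia a few tenths of a percent of time). Arrival counts are kept as
  a ground-truth event list (attribute `"events"`) so tests can verify
  rate recovery without conflating it with detection behavior: at these
  rates roughly 3% of events overlap a neighbor, and any run-length
  re-detection would merge them.
* **Hyperoxemic drifts.** Rarer (`hyper_rate` 0.4/h), lifting the signal
  just above the high bound; they register as hyperoxemia only while FiO2
  exceeds 0.21.
* **Artifacts.** Dropout runs (geometric length, mean 30 s) flagged
  invalid; invalid samples carry the last valid reading but are excluded
  from every metric and alarm computation. Caregiver FiO2 adjustments are
  flags only (about 2/day) and do not feed back into the signal.

FiO2 is a linearly declining per-subject baseline (drawn from the
configured start/end ranges, emulating weaning) plus
`controller_gain × ` the smoothed SpO2 deficit, clamped to [0.21, 1].

What the generator does **not** emulate: motion artifact with biased (not
just missing) readings, circadian structure, clustered desaturation storms,
feedback from manual adjustments, or any lung mechanics. Passing tests
therefore demonstrate the pipeline's correctness and the design's
statistical behavior on well-structured signals, not clinical performance
on real infants.

## Alarm semantics

A strategy is the triple (low threshold, high threshold, persistence
delay): tight = (range.low − 1, range.high + 1, 30 s), loose =
(range.low − 3, range.high + 3, 90 s). The monitor model in
`detect_alarms()`:

* The violation condition (valid and SpO2 beyond a threshold) must hold
  **continuously for the full delay** before the alarm annunciates; with
  5-s samples a 30-s delay means six consecutive violating samples. A
  single valid in-range sample resets the timer.
* The **audible interval starts when the delay is satisfied**, not
  retroactively at condition onset — "audible" means the annunciator is
  sounding — and ends at the first subsequent valid in-range sample.
* Invalid samples **pause** the timer by default (they neither satisfy nor
  reset the condition); `invalid_resets = TRUE` makes dropout reset it.
  Real monitors differ here and the literature does not pin this down, so
  it is a documented, configurable choice.
* Intervals are half-open `[start, end)` in sample indices; durations are
  `(end − start) × 5` s. Low and high alarms are tracked independently.

Two monotonicity properties are worth distinguishing. Increasing the delay
at fixed thresholds can never increase the event count, and the loose
strategy's *audible time* can never exceed the tight strategy's (every
loose-audible sample is tight-audible, since the loose condition implies
the tight one and its delay is longer). Widening both thresholds, however,
is **not** universally monotone in event *count*: narrowing can merge two
sub-threshold runs across a shallow recovery, so on pathological signals a
wider strategy can log more (shorter) events. On autocorrelated physiologic
signals like the generator's this essentially never happens, and the test
suite checks width monotonicity on generated series while the universal
properties are checked on adversarial random walks.

## Exposure metrics

SpO2 is integer-valued at device resolution, so "> 98%" means ≥ 99 exactly.
Hypoxemia is SpO2 < 80%; hyperoxemia is SpO2 > 98% with FiO2 > 0.21 (the
room-air comparison uses a ±0.005 tolerance). Prolonged episodes are
maximal predicate runs strictly longer than 1 or 3 minutes; an invalid
sample splits an episode. Normoxemia is 86–96%, or > 96% on room air. All
"% time" figures use valid monitored samples as denominator — the source
reports are silent on dropout handling, and this is the convention that
keeps episode durations and prevalences exactly consistent
(`Σ durations = prevalence × valid time`, a tested invariant). Hourly
medians are taken over wall-clock hours anchored at the series start, then
averaged unweighted over hours with any valid data.

## Crossover analysis

Days are assigned by 24-h alternation from a first-day label drawn with
balanced blocks of 4. Days whose recorded device settings differ from the
assigned strategy are excluded as protocol violations, as are all days of
subjects completing fewer than two; the accounting identity
enrolled = analyzed + excluded is enforced. Within subject, each metric is
recomputed over the **concatenation** of analyzed days per strategy (ratio
of summed numerators to summed denominators), not averaged over days —
pooling days first is the conservative within-subject reading of a
crossover with unequal day counts.

For each metric the within-subject tight − loose differences feed:

* **Test selection.** Shapiro–Wilk on the differences at α = 0.05 chooses
  the paired *t* (normality not rejected) or the Wilcoxon signed-rank test,
  making the usual "as appropriate" rule explicit and reproducible.
* **Wilcoxon signed-rank** with the exact distribution for n ≤ 25 without
  ties, otherwise a tie- and continuity-corrected normal approximation;
  zero differences are dropped (the Pratt variant is available via
  `zero_method = "pratt"`). An all-zero vector returns p = 1 with a
  warning rather than an error, so degenerate no-event cohorts still run.
* **Hodges–Lehmann interval.** The estimate is the median of the
  n(n+1)/2 Walsh averages; the 95% CI takes the k-th smallest and k-th
  largest Walsh averages with k the largest integer whose signed-rank
  lower-tail probability does not exceed 0.025 (normal approximation past
  n = 50). The construction is distribution-free and slightly
  conservative; at n = 20 its realized coverage is about 95%, verified by
  simulation. No multiplicity adjustment is applied, matching the
  single-primary-outcome design.
* **Power.** `power_simulation()` draws n within-subject percent changes
  from Normal(effect, SD²) and applies the two-sided one-sample t test;
  `power_paired_t()` is the noncentral-t closed form. The 75% figure is
  interpreted as the SD of the within-subject percent change — the only
  reading under which 20 subjects give > 0.80 power for a 50% reduction,
  which the simulation confirms (closed form ≈ 0.807).

## Numerical and design choices

* Derived per-subject seeds are small linear offsets of the study seed,
  kept below 2³¹; every stochastic stage (signal, randomization, exits,
  violations) draws from its own stream so that changing one does not
  perturb the others.
* Early exit is a per-day Bernoulli option (off by default): real exits
  were clinical, and a geometric model is the simplest stand-in that
  produces the "completed fewer than 2 days" exclusion path.
* Mis-set alarm days shift both recorded thresholds by ±2, which matches
  neither strategy and is therefore caught by the screen.
* Rendered tables round to the display precision of the original reports
  (0.1); all CSV outputs keep full precision.
* Test problem sizes: oracle-equivalence suites use 1,000 random series of
  40–250 samples; coverage calibration uses 1,000 replicates at n = 20;
  rate recovery uses 108 simulated subject-days; pipeline tests use 4–8
  subjects over 2–6 days. These sizes give stable verdicts (3-SE bands for
  stochastic checks) while keeping the full suite under a minute.

## Limitations

The generator is calibrated to orders of magnitude, not to any cohort's
physiology; absolute outcome magnitudes from synthetic cohorts should not
be compared against clinical reports. Signal-quality alarms (sensor-off,
low perfusion) are not modelled — the invalid-sample fraction is the only
proxy — so "audible alarm % time" here is SpO2-alarm time only, a narrower
quantity than a bedside monitor's total annunciation time. Whether a
monitor counts a re-alarm after a sub-sample in-range excursion as one
event or two is unobservable at 5-s resolution; the reset rule above is
the documented choice.
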