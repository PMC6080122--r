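---
title: "Methods: evaluating CGM measurement performance with cgmperf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating CGM measurement performance with cgmperf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmperf)
```

## Scope and model

`cgmperf` evaluates the *point accuracy* of continuous (tissue) glucose
monitoring systems against blood glucose comparison measurements, and
the *precision* between simultaneously worn sensors of the same system.
The package deliberately mirrors how such head-to-head wear studies are
analysed in practice: the question is not whether sensor and meter agree
in some abstract sense, but how far the value a user would actually have
acted on deviates from the blood value they would otherwise have
measured.

Two system classes are modelled. A *DG5-like* system stores a reading
every 5 minutes and displays exactly what it stores; its warm-up after
insertion is 2 h, its display range 40–400 mg/dL, and it is worn about
7 days, so a 14-day study uses two consecutive sensors per site. An
*FL-like* (flash) system stores a reading every 15 minutes and
additionally records a value whenever the user scans; warm-up is 1 h,
display range 40–500 mg/dL, wear time 14 days. All glucose values are
mg/dL throughout (a reader option converts mmol/L input by the factor
18.016); all times are UTC at second resolution, because the pairing
windows (±3 min, 5 min) demand sub-minute arithmetic.

## Pairing rules

Reference measurements are taken in duplicate; only the *final*
replicate of each group is evaluated (`select_final_replicates()`),
matching the rule that the last obtained result is the one used for
calibration and therapeutic decisions.

Three pairing modes connect a final reference at time $t$ to a sensor:

* **LOCF** — the latest stored value in $[t - 5\,\text{min},\, t]$.
  Both bounds are closed: a reading exactly 5 min old still qualifies.
  The underlying wording ("within up to 5 min before") is ambiguous at
  the endpoint; the closed interpretation is chosen once and tested
  explicitly.
* **SCAN** — the scan minimizing $|t_{scan} - t|$ subject to
  $|t_{scan} - t| \le 3\,\text{min}$. Exactly equidistant candidates
  break toward the *earlier* scan — the value the user saw first; the
  convention is a package decision, the sources are silent.
* **INTERPOLATED** — linear interpolation of the stored record,
  nominally to one value per minute. When the reference time is not on
  the minute grid the value is computed at the *exact* reference time
  from the bracketing records rather than snapped to the grid, avoiding
  up to 30 s of artificial mismatch. Interpolation never bridges record
  gaps longer than 30 min (configurable; 2–6× the nominal cadences):
  interpolating across a sensor outage would fabricate data.
  Flash interpolation uses continuous records only, never scans.

Warm-up periods are excluded: no pair may reference a sensor time (or a
reference time, for interval membership) before
`wear_start + warmup_minutes`. By default LOCF is applied to DG5-like
systems only — flash results are conventionally reported as scanned and
continuous-interpolated — but `build_pairs(locf_systems =)` can extend
it, since the stored flash record is also a step function to its user.

## Deviation and precision statistics

All statistics use the field's 100 mg/dL split: below it, deviations are
absolute (mg/dL); at or above it, relative (%). A reference of exactly
100 mg/dL falls in the relative stratum (the defining wording is
"<100 / ≥100"). The implemented quantities, per pair $(x, y)$ of
reference and sensor values with $\delta = y - x$:

* MAD $= \mathrm{mean}\,|\delta|$ over $x < 100$; MARD
  $= \mathrm{mean}\,|\delta|/x$ over $x \ge 100$; each as mean ±
  *population* SD (denominator $n$) of the per-pair values, with $n$.
  The combined statistic maps each pair to $|\delta|$ or
  $100\,|\delta|/x$ by stratum; the whole-range MARD ignores the split.
* Exceedance at threshold $h \in \{15, 20, 30, 50\}$: a pair exceeds iff
  $|\delta| > h$ mg/dL (below the split) or $|\delta|/x > h\%$ (at or
  above). Exceeding is *strict* so that the ISO-15197-style "within
  limits" analysis ($\le$) is its exact complement. Exceeding pairs are
  further split by sign of $\delta$ (sensor below vs above the meter).
* PAD/PARD: for two sensors $a, b$ of one system on one participant,
  both interpolated to the common minutely grid,
  $d = |a - b|$ and $m = (a + b)/2$; PAD $= \mathrm{mean}\, d$ over
  $m < 100$, PARD $= \mathrm{mean}\, d/m$ over $m \ge 100$. The
  pair-mean denominator makes the statistic symmetric; the alternative
  (one designated sensor) is not implemented because the symmetric
  convention is the established one for sensor-to-sensor comparison.

Percentages are reported rounded half-up to one decimal, and rounding is
applied *only* at the reporting layer — never inside computations — so
aggregation remains exact. Hour-scale summaries (the in-house table
cells) first pass through `thin_hourly()`, which keeps the earliest pair
per (participant, sensor, mode, clock hour), so the dynamic windows with
one reference every 15 min do not over-represent themselves; which value
per hour to retain is not specified anywhere, "earliest" is the package's
fixed choice.

Stratifiers: phase, wear day (floor of days since the sensor's wear
start), glucose range (default bins <70, 70–180, >180 mg/dL), reference
method, therapeutic decision, and trend. Trend has no published
procedure; the package computes the reference rate of change by centered
difference over the participant's adjacent final-replicate meter values
inside the dynamic phase (15-min spacing) and classifies rising
(> +1 mg/dL/min), falling (< −1), stable otherwise, with everything else
`unclassified`, so the groups still partition the input.

## Consensus error grid

Zone assignment uses the type 1 diabetes consensus (Parkes) grid. The
grid's defining publication is a consensus procedure, not a formula, so
the zone boundaries ship as data: an ordered vertex table
(`inst/extdata/ceg_type1_boundaries.csv`) of the seven transition
polylines (A|B, B|C, C|D above and below the identity line, D|E above
only), taken from the published technical description of the grid. The
implementation evaluates each polyline as a monotone function of the
reference coordinate; a point's zone is one step worse for every
boundary it strictly crosses. Three deliberate conventions:

* Points exactly *on* a boundary (including on the vertical segments of
  the lower transitions) belong to the lower-risk zone.
* The domain is $[0, 550]^2$ mg/dL; out-of-range input raises an error
  rather than being clamped, so silent distortion is impossible.
* The tests rebuild the grid as closed polygons and check the
  implementation against an independent ray-casting point-in-polygon
  oracle on $10^5$ random points, plus partition and
  monotone-risk properties, so a future re-digitization of the vertex
  file is immediately re-validated.

## The synthetic study generator

The generator produces the *structure* the analysis assumes, not a
physiological simulation. Defaults encode the emulated design: 20
participants, 14 days (day indices 0–13), clinic visits on the half-open
day windows [0,2), [5,7), [12,14) — i.e. 3 × 48 h in-house with 72 h and
120 h home-use phases between — dynamic mornings on days 1, 6, 13,
meter measurements hourly 06:00–24:00 plus one nightly while in-house
(19 groups/day), every 15 min from 30 min before breakfast to 5 h after
on dynamic mornings (23 groups, measured by both the meter and a venous
laboratory method), five per day at home, and therapeutic-decision flags
at the three daily meal times.

True glucose is phenomenological: baseline 120 mg/dL + a 10 mg/dL
circadian sinusoid + gamma-shaped meal responses (peaks 80/60/70 mg/dL,
45 min to peak) + a stationary Ornstein–Uhlenbeck fluctuation (SD
6 mg/dL, 30 min mean reversion), at 1-min resolution, clamped to
[40, 450]. On dynamic mornings the breakfast response is enlarged
(170 mg/dL) and followed by a delayed insulin-response dip (120 mg/dL,
peaking 3.5 h after breakfast), sized so the excursion deterministically
passes 250 mg/dL and later falls below 70 mg/dL inside the dynamic
window — the generator *guarantees* the designed excursion rather than
sampling for it. No insulin–glucose ODE model is attempted; the process
only needs realistic levels and rates of change.

Sensors see a first-order lag filter of the true profile
($\tau$ = 8 min by default, motivated by blood-to-tissue kinetics),
implemented by the exact exponential integrator for piecewise-linear
input — on a ramp of slope $r$ the steady-state deviation is exactly
$-r\tau$, which the tests verify to $10^{-9}$. Sampling at the system
cadence is anchored at wear start; noise is
$y = T\,(1 + \varepsilon_p) + \varepsilon_a + b$ with
$\varepsilon_p \sim N(0, 0.09^2)$, $\varepsilon_a \sim N(0, 3^2)$,
$b = 0$ by default, then display clamping, then i.i.d. dropout
(p = 0.01). Scans are generated at the participant's meter-measurement
times plus uniform jitter of ±2 min, deliberately exercising the ±3 min
matcher near its edges; scans are a deliberate user action and are not
subject to dropout. The default noise/lag values are illustrative — they
land aggregated MARD in the ~9–11 % range typical of the emulated
devices — and are *not* estimates of any real sensor; no published error
decomposition exists for them.

Meter references get proportional error SD 0.025 (venous: 0.02, no
bias). Duplicates violating the 10 mg/dL/10 % concordance rule (assessed
against the replicate mean) trigger a third, freshly drawn replicate —
values are regenerated, not truncated — and the last replicate is
flagged final. All random streams derive from the master seed by a
counter scheme (one stream per participant profile, reference set and
sensor), so partial regeneration is reproducible and full regeneration
is byte-identical.

**What a green test does and does not establish.** The generator
reproduces the design's schedule, cadences, duplicate logic, warm-ups,
replacement, and a plausible error structure; it does not reproduce
calibration dynamics, compression artifacts, day-one insertion effects,
interferents, or real between-sensor correlation. End-to-end tests
therefore validate the *analysis pipeline* (a zero-error world must
yield exactly zero deviations; known injected noise must be recovered at
its closed-form value; lag must degrade dynamic phases), not any claim
about real device performance.

## Numerical and degenerate-input choices

* Empty strata are reported as `NA` with n = 0 (rendered "n.d."), never
  dropped silently; empty inputs yield defined zero-count results.
* `round_half_up()` implements ties-away-from-zero decimal rounding,
  since `round()`'s banker's rounding cannot reproduce reported
  percentage tables.
* Validation is total: every malformed input produces a structured error
  naming the trace and row numbers; readers never clamp or repair.
* Aggregation across evaluation units is exact: per-unit n sum to the
  aggregated n and the aggregated mean is the n-weighted mean of unit
  means (tested to $10^{-9}$); pooled SDs combine via
  $E[X^2] - (E[X])^2$.
* The zero-error identity holds *exactly* (not within a tolerance)
  because the schedule grid is aligned with both sampling cadences and
  the all-zeros error model also zeroes the scan-time jitter.

## Known limitations

* The error model has no autocorrelated sensor noise and no drift
  between calibrations; PARD on synthetic twins is therefore slightly
  idealized.
* The consensus grid is the type 1 variant only; the type 2 grid and
  other error grids (Clarke, surveillance) are out of scope.
* No between-system hypothesis testing is provided; the analysis is
  descriptive/exploratory by design.
* In-house/home-use phase boundaries are crisp in the synthetic world;
  real data must arrive with phases already annotated.
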