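---
title: "Methods: chest-compression quality metrics, decay classification and the no-flow ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chest-compression quality metrics, decay classification and the no-flow ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprquality)
```

## The problem

During cardiopulmonary resuscitation, survival depends on chest-compression
quality: adequate compression depth, a compression rate inside the guideline
band, and as little hands-off ("no-flow") time as possible. Resuscitation
guidelines recommend rotating the compression provider every two minutes on
the assumption that rescuers fatigue quickly, yet rescuers differ enormously
in how they compress from the very first minute. Whether an individual
rescuer's quality *decays* over a prolonged attempt is therefore best judged
per rescuer, against their own starting quality, not by cohort mean curves
that mix strong and weak starters.

`cprquality` implements that per-rescuer analysis for time-stamped
compression event streams, one stream per resuscitation attempt: each record
is one delivered compression with its time (seconds from scenario start) and
peak sternal displacement (mm). The package covers a 12-minute advanced life
support (ALS) scenario by default, the span over which prolonged single-provider
compressions are of interest.

## Per-minute reduction

Minute $m \in \{1,\dots,12\}$ covers the half-open window
$[60(m-1), 60m)$ s, so no compression is counted twice.

* **Depth**: the arithmetic mean of the peak depths of the compressions in
  the window; undefined (`NA`) when the window has no compressions.
* **Rate**: the *instantaneous* (active-compression) rate
  $60/\overline{\Delta t}$, where $\overline{\Delta t}$ is the mean of the
  inter-compression intervals attributed to the window. Intervals longer
  than the pause threshold (below) are hands-off time and excluded; an
  interval spanning a minute boundary is attributed to the minute containing
  its midpoint — a deterministic, unbiased tie-break.

The active-rate definition matters: an attempt can compress at 110/min
while still having a 20 % no-flow ratio, because rate describes the cadence
*during* compressions while the no-flow ratio describes how much time had
none. Defining rate as compressions per elapsed minute would conflate the
two. A minute with no compressions has undefined depth and rate, and an
undefined metric fails every quality criterion — a minute without
compressions cannot have delivered adequate ones.

Attempts longer than the analysis span are truncated at 720 s; shorter
attempts are an error by default, since the decay definitions need the full
span, with `allow_short = TRUE` analysing complete minutes only.

## Good, bad, decay

Quality thresholds follow the 2005 resuscitation guidelines: depth at least
40 mm, rate within 100–120/min, both bands inclusive and compared on exact
stored values ("≥ 40 mm" means 40.0 passes). The 2010-guideline 50 mm floor
is available by setting `cpr_thresholds(depth_min_mm = 50)`.

For each dimension independently (an attempt can be depth-good and
rate-bad):

* **good** — the criterion holds in every analysis minute;
* **bad** — the criterion already fails in minute 1. "Initial" quality is
  minute 1's average, the finest granularity of the per-minute reduction,
  and the bad label is frozen there: an attempt that starts too shallow but
  reaches adequate depth mid-attempt stays bad, because it never showed
  compliant-then-deteriorating behaviour;
* **decay** — minute 1 complies but a later minute does not; the onset is
  the first failing minute. Decay is the operational proxy for fatigue:
  quality that was achievable at the start and then was lost.

These three labels partition any cohort, and raising a threshold can only
move an attempt along good → decay → bad, never backwards — both properties
are enforced by the test-suite over random trajectories.

## Hands-off pauses and the no-flow ratio

The no-flow ratio (NFR) is time without chest compressions divided by total
scenario time. "Without compressions" is operationalised with a gap
threshold: any maximal compression-free interval longer than
`pause_threshold` is a pause, including the leading interval from scenario
start to the first compression (the initial patient assessment is genuine
no-flow) and the trailing interval to the end of the span. The default
threshold is 1.5 s — the conventional choice in the CPR-quality literature,
roughly three times a normal inter-compression interval at 110/min — and it
is a configuration knob, as is the leading-interval convention, since
recording devices differ on both. When a gap exceeds the threshold the
whole gap counts as hands-off, not just the excess; this keeps NFR monotone
in gap insertion.

NFR is analysed in four 3-minute windows (boundaries at 0/180/360/540/720 s,
the Norwegian-guideline rhythm-check cycle), pauses being split at window
boundaries. Because the windows tile the span exactly, window hands-off
seconds sum to the total and the overall NFR equals the mean of the four
window ratios.

## Trend statistics

The cohort NFR trend over the four periods is tested with a one-way
repeated-measures ANOVA (subjects = attempts, conditions = periods) using
the standard within-subject decomposition

$$SS_{\text{error}} = SS_{\text{total}} - SS_{\text{subjects}} - SS_{\text{conditions}},
\qquad
F = \frac{SS_{\text{cond}}/(k-1)}{SS_{\text{err}}/((k-1)(n-1))},$$

followed by paired t-tests of period 1 against each later period at the
Bonferroni-adjusted level $0.05/3 \approx 0.017$. The sums of squares and
the t statistic are computed from these formulas directly (only the
distribution tails come from `stats::pt`/`pf`) so the decomposition is
testable against an independent brute-force oracle; `stats::aov` and
`stats::t.test` serve as cross-checks in the suite, not as the
implementation. Tests are two-sided — the conservative default where
sidedness is not dictated — and no sphericity correction is applied by
default, matching how such designs are conventionally reported;
`sphericity_correction = TRUE` applies Greenhouse–Geisser scaling for users
who want it. Degenerate inputs fail loudly: an all-constant matrix or a
zero-variance nonzero difference is an error, while identical paired
vectors legitimately give $t = 0,\ p = 1$ and a matrix with only
subject-level shifts gives $F = 0$.

## The synthetic generator

`generate_attempt()` lays compressions down sequentially: from a compression
at time $t$ the next follows after $60/\text{rate}(t)$ seconds, with
per-compression Gaussian rate noise, and per-compression depth noise
truncated at zero — the simplest model consistent with the within-provider
spread seen in real recordings. Scheduled pauses (assessment,
defibrillation, rhythm checks, intubation) interrupt the stream; the
generator emits a compression exactly at each pause boundary, so the
analyzer-measured hands-off gap equals the scheduled duration exactly and
NFR expectations can be engineered by construction.

The parametric depth model holds the provider's baseline until the
configured decay-onset minute, then declines linearly *from the reference
depth* (40 mm by default) with the configured slope, so the onset minute's
mean is $40 - |\text{slope}|/2$ and a threshold classifier recovers the
configured onset. Anchoring the decline at the reference rather than at the
baseline is deliberate: decay labelling is about crossing the guideline
floor, and a decline anchored at an arbitrary baseline would cross the
floor $(\text{baseline}-40)/|\text{slope}|$ minutes late, making
"configured onset" meaningless as a recoverable parameter. The price is a
stylised discontinuity at onset (quality "gives way" rather than eroding
smoothly); for arbitrary trajectory shapes an explicit per-minute profile
(`depth_profile_mm`, `rate_profile`) overrides the parametric model.
Parameter recovery is verified by simulation: with slope ≥ 1 mm/min and
noise ≤ 1 mm the classifier recovers the configured onset within ±1 minute
in well over 95 % of seeds (200-seed runs in the test-suite).

## The reference cohort

`reference_cohort()` generates a fixed-seed cohort of 19 simulated
attempts (master seed 20110809) whose *group structure* matches the study
cohort the package's definitions were built around: depth groups
5 good / 9 bad / 5 decay with decay onsets at minutes 2, 4, 8, 11 and 12
and one bad attempt adequate only during minutes 3–8; rate groups
6 good / 6 bad / 7 decay with exactly one rate-decay onset within five
minutes, two rate-bad attempts in-band from minute 2 onwards and five
attempts starting above 120/min; window NFR means of 22/22/14/10 % with a
17 % overall mean and per-attempt overall NFR spanning 10–32 %.

Everything finer than that structure is invented: the per-minute profile
values, the pause-duration splits (scaled per attempt from a common
assessment/shock/rhythm-check/intubation narrative, with interruptions
shrinking after intubation at ~285 s because a secured airway allows
compressions through ventilations), and the noise levels (depth SD 1.2 mm,
rate SD 3/min, chosen so that minute means are determined by the profiles
with wide margins). These are hand-tuned constants shipped with the code —
synthetic data, not a measurement record — and reproducing the group
structure on this fixture demonstrates that the pipeline's definitions and
arithmetic are faithful, **not** that the package has validated anything
about real resuscitations. The generator also does not emulate features of
real recordings such as variable chest stiffness, leaning/incomplete
release, provider switches, or waveform-level noise; passing tests say
nothing about those.

## Numerical choices and limitations

* Window membership uses half-open intervals throughout; events exactly on
  a boundary belong to the later window, pauses are clipped exactly at
  window edges, and all comparisons are on exact doubles with no rounding
  before thresholding. Human-readable reports round percentages to
  integers; machine outputs keep full precision.
* Problem sizes in the shipped tests: 19-attempt cohorts, 100–200 random
  matrices or seeds per property, streams of a few hundred events — the
  whole suite runs in well under a minute.
* File I/O writes numbers with `%.17g`, so written files are byte-stable
  and round-trip to bit-identical doubles.
* The per-attempt CSV dialect is this package's own; proprietary
  manikin/defibrillator formats must be converted upstream. Ventilation
  rows are accepted and counted but never analysed.
* Statistical machinery assumes complete, balanced data (every attempt
  contributes every period); there is no missing-data handling, and no
  mixed-model or non-parametric alternative to the repeated-measures ANOVA.
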