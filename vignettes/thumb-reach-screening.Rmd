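---
title: "Thumb-reach kinematics and CTS screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thumb-reach kinematics and CTS screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thumbscreen)
```

## The measurement

Carpal tunnel syndrome (CTS) compresses the median nerve at the wrist; in
advanced stages the thenar muscles waste and thumb opposition becomes slow
and clumsy. `thumbscreen` analyses a tablet game built around exactly that
motion: the player holds the tablet with the fingers fixed and slides only
the thumb from a central circle to targets arranged like the numerals of a
clock. Each session reduces to 36 numbers per hand -- for each of the 12
clock directions, the reach's maximum speed (cm/s), average speed (cm/s)
and total time (s).

## Protocol model and geometry

A `game_layout()` fixes the geometry in screen centimetres: targets on a
circle of radius 3.5 cm around the centre, target radius 0.6 cm, central
return circle of radius 0.8 cm, and a 3 s appearance timeout. None of these
dimensions is canonical -- they are plausible hand-held-tablet values, all
overridable -- and every downstream statistic is reported in cm/s and s so
results scale with the configured geometry. Direction `k` is the
`k`-o'clock bearing: 12 o'clock points up and indices advance clockwise in
30-degree steps.

Targets appear one at a time in a seeded random order
(`make_target_schedule()`). A target is *collected* when a touching sample
falls within the target radius of its centre, and *missed* when the
appearance timeout elapses; a missed target reappears once, immediately
(whether the original app re-randomised the order after a miss is unknown;
immediate reappearance is the simplest protocol consistent with "appears
twice"). Between directional targets a return-to-centre target guides the
thumb back. `validate_session()` checks the full event grammar -- direction
coverage, strictly increasing timestamps, resolution after appearance, and
second appearances only after a miss -- returning all violations as data
rather than stopping at the first.

## Segmentation and the clock-start convention

The scored window for a direction is the appearance on which its target was
collected (the second, if the first was missed); if both appearances were
missed, the first window is scored as a degraded reach. Within the window:

* **Start** (`t_start`): the first crossing of the central circle's
  boundary, located by linear interpolation between the straddling samples.
  Whether "total time" should start at target appearance (including
  reaction time) or at movement onset is a genuinely open choice; we start
  the clock at centre exit, so dwell and reaction inside the circle are
  excluded. Comparisons against absolute published times inherit this
  convention, but the shipped calibration is self-consistent with it.
* **End** (`t_end`): the first touching sample inside the target disc, or
  the timeout for a miss.

A recording in which the thumb never registers inside the centre during the
window falls back to the first touching sample as the start, so degraded
recordings still segment; a window with no touching samples at all is an
error naming the direction.

## Kinematics

Speeds come from raw finite differences -- Euclidean displacement over the
time step between consecutive in-contact samples -- with no filtering,
because the recording pipeline being modelled applies none. `max_speed` is
the largest instantaneous speed, `avg_speed` is path length over reach
duration, and `total_time` is `t_end - t_start`. Lift-off gaps
(`touching = FALSE`) contribute no path length (a capacitive screen cannot
see a lifted thumb) but the clock keeps running. An optional 3-sample
moving average of positions (`smoothing = TRUE`, off by default) is
available for noisy digitisers; it can only lower measured peaks. These
definitions guarantee `max_speed >= avg_speed` per reach, time-rescaling
equivariance (doubling all timestamps halves speeds and doubles durations)
and rotation invariance of per-reach parameters -- all enforced as
property tests.

The canonical feature order is direction-major:
`d00_maxspeed_cmps, d00_avgspeed_cmps, d00_totaltime_s, ...,
d11_totaltime_s`, which is also the CSV column order.

## The synthetic cohort generator

No raw patient recordings are publicly deposited, so the simulator is a
first-class module: it generates full touch streams, and everything
upstream of the statistics is tested through them.

**Reach model.** Human point-to-point reaches have bell-shaped speed
profiles; the minimum-jerk profile `v(tau) = 30 tau^2 (1-tau)^2 L/T` is the
standard idealisation and has a fixed peak/mean ratio of 1.875. The
published per-direction medians, however, imply max/avg ratios from about
1.06 to 2.37 -- slow, hesitant CTS reaches are *peakier* than minimum jerk.
The simulator therefore uses the generalised bell
`v(tau) proportional to (tau (1 - tau))^p` (the Beta(p+1, p+1) density in
normalised time; `p = 2` is exactly minimum jerk), whose peak/mean ratio
`4^{-p} / B(p+1, p+1)` increases continuously from 1, and solves `p` per
reach to match the drawn ratio.

Each reach draws total time, average speed and peak/average ratio from
log-normal distributions (positive support, right skew). The path is a
sine-bowed curve from the centre-circle edge to the target-disc edge whose
bow amplitude is solved numerically so the arc length equals
`avg_speed x total_time`; the bow side is random. Sampling is at 60 Hz
(typical capacitive touchscreen, configurable) with an exact final sample
at target contact, so the extracted `total_time` reproduces the drawn value
to within one sample period. Draws implying a path shorter than the
straight reach, or a ratio at or below 1, are redrawn (at most 100 times;
the truncation biases recovered medians by a few percent in the most
constrained cells, well inside the calibration tolerance).

**Calibration.** The shipped profiles set each direction's three medians to
the published group medians, and the log-normal sigma so that the 2.5th and
97.5th population quantiles span the printed intervals:
`sigma = (log hi - log lo) / (2 x 1.96)`. The printed intervals are 95% CIs
of *medians*, not population quantiles, so this deliberately conservative
reading understates population spread; exact population dispersion is
unrecoverable from the published summaries. Reaction time (appearance to
centre exit) is log-normal with median 0.25 s (0.30 s for the CTS profile)
-- ordinary simple-reaction values -- and never enters a scored feature
under the centre-exit convention. The default miss probability is 0.05 per
appearance: misses are protocol noise, not a published quantity, and this
keeps second appearances present but rare.

**What the simulator does not model.** Tremor, fatigue drift, multi-touch,
device-specific jitter, within-patient correlation between two hands, and
any coupling between features beyond the shared draw per direction. Passing
the parameter-recovery and power tests therefore shows the *pipeline* is
correct and the effect sizes detectable at the published sample sizes -- it
does not show that real hands behave like the generator.

**Parameter recovery.** The loop simulator -> segmentation -> extraction is
closed by requiring that, over 200 simulated hands per group, the cohort
median of every extracted feature lands within 10% of its configured
median, for all 72 group x direction x parameter cells. 200 hands puts the
sampling noise of a median near 2-3%, leaving honest headroom for the
small discretisation and truncation biases.

## Group statistics

`compare_groups()` mirrors the original analysis: one Welch two-sample
t-test per cell (36 cells), two-sided, flagged at p < .05 with **no**
multiple-testing correction -- a deliberate reproduction of the per-cell
reading, annotated as such rather than corrected. Two hands of one patient
are treated as independent observations, again mirroring the original
analysis; a clustered or mixed-model treatment is out of scope. The 95% CIs
of medians use a seeded percentile bootstrap (default 10,000 resamples):
the original interval construction is unstated, and the percentile
bootstrap is simple, distribution-free and reproducible. Its coverage for
log-normal samples of the study's size is verified by simulation in the
test suite.

## The screening classifier

A two-class SVM with nested hyperparameter search:

* **Grid**: linear and radial-basis kernels; cost `2^{-5, 0, 5, 10}`;
  radial width `2^{-9, -5, -1}`. Coarse log-spacing is a deliberate cost
  trade-off: selection runs leave-one-out *inside* every outer fold
  (O(n^2) fits per grid point), mirroring the outer validation style.
* **Scaling**: features mix cm/s and s, so each fold standardises with
  training-fold statistics only; the held-out hand never contributes.
* **Tie-breaking**: equal inner accuracy resolves toward smaller cost, then
  the linear kernel, then smaller width -- the simplest model. A held-out
  hand exactly on the decision boundary is called CTS: a screening test
  prefers a false alarm over a missed case.
* **Imbalance**: no class weighting by default (the 29 vs 11 design was
  analysed unweighted); a weighting flag exists.

Whether the original grid search was nested inside the cross-validation is
unstated; nesting is the leakage-free choice, so published headline
accuracies may correspond to the slightly optimistic unnested variant. The
published 93% sensitivity / 73% specificity cannot be reproduced without
the patient recordings, so the classifier is validated by construction
instead: perfect LOOCV on margin-separable Gaussian clusters (4 SD mean
shift per feature) at the study's 29 + 11 sample sizes, chance-level
balanced accuracy under label permutation (no leakage), and row-order
invariance of predictions. Decision values from the underlying libsvm
solver are order-sensitive at its convergence tolerance (~1e-3), so exact
invariance is asserted on labels, approximate on values.

## Numerical choices

* Inside/outside tests on circles use a 1e-9 cm tolerance, so points
  constructed exactly on a boundary classify deterministically.
* The bow amplitude and bell exponent are solved by `uniroot` to 1e-9 on
  129-point trapezoid quadrature of the arc length; the residual
  path-length discretisation error at 60 Hz is well under 1%.
* Bootstrap and simulation seeds are explicit everywhere; per-hand seeds
  derive from a master seed, so cohorts are bitwise reproducible.
* Degenerate inputs fail loudly: duplicate timestamps, zero-variance Welch
  samples, missing directions, non-finite features, and classes too small
  to leave both represented in every training fold are all errors naming
  the offender.

## Problem sizes used by the checks

The shipped verification uses 200 hands per group for calibration recovery,
200 replicate cohorts at the published 11 + 29 sample sizes for the power
check on the 6 o'clock average-speed deficit, 1,000 sample pairs for the
Welch oracle and 1,000 null replicates for its type-I error, 50 label
permutations for the leakage check, and 10,000 simulated reaches for the
kinematic inequality. These sizes keep each Monte-Carlo standard error a
few times smaller than the tolerance it guards.

## Known limitations

The dispersion calibration is approximate by construction (see above); the
simulator's independence assumptions make the synthetic classification task
easier than the clinical one, so classifier results on synthetic cohorts
overstate clinical accuracy; the centre-exit clock start is one of two
defensible conventions; and the statistics layer intentionally reproduces
the original uncorrected, unclustered analysis rather than improving on it.
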