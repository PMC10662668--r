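---
title: "Simulating and evaluating picture-pointing preschool hearing screens"
author: "hearscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating picture-pointing preschool hearing screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearscreen)
```

## The problem

Screening 4–5-year-old children for hearing loss ordinarily requires a
pediatric audiologist, a calibrated audiometer and a soundproof booth, all of
which are scarce outside referral hospitals. A tablet-based alternative plays
a two-syllable word (a spondee) over headphones at a fixed hearing level and
asks the child to point at the matching picture among six; descending the
level from 40 to 30 to 20 dB HL and requiring 2 correct answers out of up to
3 picture sets per level yields a coarse per-ear threshold in about a minute
and a half. Validation studies compare this screen, run with several
headphone types in an ordinary quiet room, against conditioned play
audiometry in a booth, summarising the paired per-ear categories with
percent agreement, Cohen's κ, and sensitivity/specificity with exact
binomial confidence intervals.

`hearscreen` implements both halves of that pipeline: a seeded simulator of
the screen (virtual children, headphone acoustics, the adaptive test engine)
and the diagnostic-accuracy statistics, including the exact reconstruction
of 2×2 tables from the summary statistics such studies print.

## Hearing-level semantics

An ear's reference state is its air-conduction pure-tone audiogram at 0.5,
1, 2, 3 and 4 kHz. Categories follow pediatric screening guidelines with
inclusive boundaries: PTA ≤ 20 dB HL is *normal*, 20 < PTA ≤ 40 *mild*,
PTA > 40 *moderate*. The reference classifier in this package uses the
five-frequency pure-tone average, matching how reference audiometry
summarises an ear against a screener that estimates a single per-ear level;
`ear_category(method = "worst")` offers the worst-single-frequency rule for
sensitivity analyses, since validation reports do not always state which
rule was applied. Reference measurements are quantized to the audiometer's
5 dB step *before* averaging, as in clinical practice; no rounding is
applied before classification.

The screen itself cannot observe a continuous threshold. Passing 20 dB HL
maps to *normal*; a lowest pass of 30 or 40 maps to *mild* (the screened
threshold lies in (20, 40]); failing even 40 dB HL implies a level above
40, i.e. *moderate*. On the protocol grid {20, 30, 40} this mapping agrees
exactly with `classify_hearing_level()`.

## The response model

A child's answer at presentation level $x$ (dB HL) for an ear with
threshold $\theta$ follows the standard m-alternative forced-choice
psychometric function

$$\psi(x) = \gamma + (1 - \gamma - \lambda)\,F\!\left(\frac{x - \theta}{\sigma}\right),$$

with $F$ the logistic. Six pictures per set fix the chance floor at
$\gamma = 1/6$: even a profoundly deaf ear "passes" a single set with
probability 1/6, which is why the 2-of-3 criterion matters — guessing
through a whole level happens with probability
$3\gamma^2(1-\gamma) + \gamma^3 \approx 0.074$. The remaining parameters
are simulator assumptions, not measured quantities (no behavioral noise
estimates for this age group are published): lapse rate $\lambda = 0.02$
and slope $\sigma = 4$ dB are typical of young children in forced-choice
speech tasks, and each presentation independently times out (no answer
within 10 s) with probability $\tau = 0.01$. All four are explicit
`psychometric_params()` and should be varied in sensitivity analyses.
$\sigma = 0$ is accepted as the deterministic step-function limit of the
logistic, which the test suite uses to isolate protocol logic from
behavioral noise.

The level entering $\psi$ is the *effective* level from the acoustics
module, so calibration error and room noise propagate into responses. The
spondee threshold of an ear is taken to be its five-frequency PTA; flat
default audiograms make the choice of frequency weighting immaterial.

## Acoustics

Word stimuli are RMS-equalized (`equalize_rms()`) and carry per-word,
per-level calibration coefficients — the additional gain that makes the
device output match the reference audiometer's A-weighted peak through a
coupler (`calibration_coefficient()`). The physical measurement chain is
out of scope; the simulator reduces it to a scalar residual error with
optional zero-mean jitter (`test_conditions(cal_error, cal_error_sd)`,
default 0).

Room noise is handled by a deliberately transparent masking model:
`effective_level = nominal + cal_error − max(0, ambient − isolation −
offset)` with a 10 dB masking offset. In the default 35 dBA quiet room a
30 dB-isolation headphone loses nothing; a 20 dB-isolation headphone also
loses nothing until ambient exceeds 30 + offset. This is a modelling knob,
not a psychoacoustic claim: real masking is frequency- and
bandwidth-dependent. The three shipped `headphone_preset()`s carry the
impedance, sensitivity, distortion and passive isolation (30 / 20 / 30 dB)
of the supra-aural audiometric reference, a closed studio headphone, and a
generic earmuff headphone.

## The test engine

`run_ear()` walks the levels in descending order. Within a level
(`run_level()`), any timeout fails the level immediately — the protocol
treats a non-response as a failure for that level rather than as one
incorrect answer — and otherwise 2 correct answers pass. Early stopping
(after 2 correct or 2 incorrect of 3) is on by default; published protocol
descriptions state the 2-of-3 criterion but not whether the third set is
always shown, so the always-3 variant is kept behind
`protocol_config(early_stop = FALSE)`. Descent stops at the first failed
level, so at most 9 presentations occur per ear. Whether a timeout should
abort the whole test or only the current level is ambiguous in protocol
descriptions; it is implemented as a level failure with the descent ending
there, consistent with the decision flow of the protocol diagram.

Per-presentation response time is drawn from a lognormal with median 5 s
(sdlog 0.5) truncated at the 10 s window, plus 2 s of fixed inter-trial
overhead. These defaults were chosen once so that simulated two-ear totals
fall in the 46–150 s band reported for tablet screens of this design
(typical simulated means ≈ 85–90 s); they affect duration statistics only,
never pass/fail.

## The synthetic cohort

`generate_cohort()` assigns each child a status multinomially — 70%
bilaterally normal, 21% unilateral loss, 9% bilateral loss, the composition
observed in a 44-child validation cohort — and draws flat per-ear
thresholds: normal ears from Normal(10, 5) truncated to [−10, 20] dB HL,
mild ears Uniform(25, 40), moderate ears Uniform(45, 70). Loss ears are
moderate with probability 0.2, a value chosen once to reflect that the
reconstructed reference tables contain only a single moderate ear among
roughly 17 loss ears; the mild/moderate split is never printed directly, so
this is explicitly a configurable assumption. The mild band starts at 25
rather than 20.01 dB because behaviorally measured mild losses cluster away
from the screening boundary; note this makes the generator slightly kind to
the screen at the normal/mild boundary, which is one reason simulated
agreement runs higher than the published mild-row agreement.

The simulated reference (`reference_test()`) adds Normal(0, 2.5) dB
measurement noise per frequency — a typical behavioral test–retest spread,
small relative to the 5 dB step it is then quantized to — computes the PTA
and classifies it. Reference durations are lognormal per ear (meanlog
log 275, sdlog 0.25), putting two-ear totals in the several-hundred-second
range reported for conditioned play audiometry (421–1152 s).

What the generator does *not* emulate: per-frequency audiogram shape
(optional jitter exists but defaults to 0), conductive vs sensorineural
etiology, cerumen effects, attention drift over a session, and word-to-word
difficulty differences. Passing simulation tests therefore demonstrates the
protocol's decision logic and the statistics, not field performance of any
real device.

## Statistics

All agreement statistics operate on `two_by_two(a, b, c, d)` tables built
by one-vs-rest dichotomization per category (`confusion()`), mirroring the
three-row-per-headphone layout validation reports use. Cohen's κ is
computed from observed and margin-expected agreement; its p-value is the
large-sample z test of κ = 0 using the null standard error from the
margins (reports in this literature print κ p-values without naming a
method; this is the standard choice). When one rater is constant the null
variance vanishes and the z test is undefined (`NA`), though κ itself may
still be defined. Sensitivity and specificity carry Clopper–Pearson exact
intervals in beta-quantile form; `mcnemar_exact()` is the exact two-sided
binomial test on discordant pairs; durations are compared with a paired t
test. Percentages are carried on the 0–100 scale throughout, matching how
such results are printed.

### Reconstructing tables from printed summaries

An exact binomial CI is a fingerprint of the integer pair (successes,
trials): 2.5–100 can only be 1/1, 6.76–93.2 only 2/4. Given a printed
sensitivity with its CI, the screener-positive row count, and N,
`reconstruct_from_summaries()` enumerates every candidate reference margin
and success count, keeps those whose recomputed summaries round (half-up,
at the printed precision) to the printed values, and errors distinctly on
zero or multiple survivors. For the moderate-loss rows of the motivating
88-ear dataset this inversion is unique and yields tables (1, 7, 0, 80),
(1, 5, 0, 82) and (1, 6, 0, 81), whose κ (0.206, 0.272, 0.235), agreement
and specificity reproduce the published values exactly. The corresponding
mild and normal rows are *not* jointly consistent with N = 88 under any
dichotomy tested (e.g. agreement percentages that are not expressible as
k/88), so they are deliberately excluded from reconstruction; the
reconstruction code is instead property-tested as a left inverse of
`sens_spec()` on random tables.

### The kappa paradox

Those same tables show 92–94% agreement with κ ≈ 0.2: with 87 of 88 ears
reference-negative, expected agreement is already ≈ 0.9 and κ's numerator
has almost no room. `kappa_paradox_report()` quantifies this with the
prevalence index (a−d)/N, bias index (b−c)/N and PABAK = 2·po − 1 (0.841
for the first table), flagging tables whose κ is low despite high
agreement. κ remains the right headline statistic — PABAK answers "what if
prevalence were balanced", which it is not — but the report makes the
mechanism visible.

## Numerical choices

* Printed-value matching uses round-half-up at the printed number of
  decimals (the convention of the statistical software that produced such
  tables), not R's round-half-even.
* Audiometric quantization is half-up to the 5 dB grid.
* Category boundaries are applied to un-rounded PTAs.
* Seeds: every stochastic entry point takes an explicit seed; multi-part
  pipelines derive independent substreams (`sample.int` from the master
  seed) per child, per ear and per pipeline stage, so one component's draw
  count cannot perturb another's.
* Degenerate inputs fail loudly: silent waveforms, empty frequency sets,
  single-category κ tables, empty sens/spec margins, zero-variance paired
  differences.

## Problem sizes used in validation

The shipped tests exercise: the exhaustive noiseless threshold grid 0–80 dB
in 1 dB steps against a brute-force decision-tree oracle; cohort prevalence
recovery by χ² at 10,000 children; 200 replicate 44-child studies (median
moderate-loss sensitivity 100%, median specificity ≥ 90% under default
noise); 1,000 random tables against an enumeration κ oracle; and all
Clopper–Pearson endpoints for n ≤ 30 against a cumulative-binomial
root-finder. These sizes give stable verdicts at interactive runtimes.

## Known limitations

* The masking model is a scalar threshold shift; it cannot represent
  spectral masking or distortion at high output.
* Flat audiograms make the PTA-vs-worst-frequency distinction vacuous by
  default; enable `jitter_sd` to study it.
* The κ p-value is asymptotic; at N = 88 with extreme margins it is an
  approximation (the motivating values reproduce nonetheless).
* Simulated children do not fatigue or learn, so the logged test-order
  randomization cannot influence outcomes as it might in the field.
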