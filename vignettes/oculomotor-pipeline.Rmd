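---
title: "Models and methods behind saccadeflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind saccadeflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccadeflow)
```

saccadeflow analyses prosaccade/antisaccade batteries and resting
pupillometry from crossover pharmacology studies. This vignette documents
the models it fits, the preprocessing conventions it fixes, the synthetic
cohort generator that backs its tests, and the design decisions taken where
the conventions of the field leave room.

## The main-sequence model

Saccades obey a stereotyped amplitude–velocity relationship (the "main
sequence"): peak velocity rises with amplitude, approximately linearly for
small saccades and saturating for large ones. Over the 1.5°–10° range this
pipeline admits, we model it as a one-parameter square-root law,

$$y = V \sqrt{x},$$

with $y$ the peak velocity (deg/s), $x$ the absolute amplitude (deg), and
$V$ (deg·s⁻¹·deg⁻¹ᐟ²) the coefficient of interest. The single-parameter
form is deliberately parsimonious: with a few hundred trials per group, a
one-parameter curve is estimable per condition without the instability of
two-parameter saturating fits. Least squares gives the closed form
$\hat V = \sum_i y_i \sqrt{x_i} \big/ \sum_i x_i$ (`fit_sqrt()`),
assuming independent, roughly homoscedastic velocity errors across trials.

Uncertainty comes from a case-resampling bootstrap (`bootstrap_v()`,
default 1000 resamples): trials are resampled with replacement, the closed
form is refit, and $V$ is reported as the bootstrap median with a 2.5/97.5
percentile interval. Resampling is unstratified across trials by default —
matching the trial-level reading of the analysis — with within-subject
stratification available via `strata=` for users who prefer to respect the
subject hierarchy.

Deviation from a normative curve is scored per saccade
(`delta_peak_velocity()`): $\Delta_i = y_i - V_{\mathrm{ref}}\sqrt{x_i}$,
where $V_{\mathrm{ref}}$ is a *frozen* reference (a control group's fit),
evaluated continuously at the observed amplitude, never binned, and never
the group's own fit (a group's $\Delta$ against its own fit is orthogonal
to $\sqrt{x}$ by construction and tests nothing). The $\Delta$ values are
tested against zero with a trial-level one-sample t-test and a JZS Bayes
factor; treating trials as independent is an approximation that ignores the
subject hierarchy and is consistent with reporting the test at trial-level
degrees of freedom. Users who need hierarchy-aware inference can feed the
exported tidy trial tables (`primary_saccades.tsv`, `deltas.tsv`) into a
mixed-effects package; such models are intentionally outside this package.

## Trial parsing conventions

The primary saccade of a trial is the first detected saccade with amplitude
strictly between 1.5° and 10° and latency strictly between 90 ms and
2500 ms; the lower gates exclude microsaccades and anticipations, the upper
ones off-screen saccades and inattention. The inequalities are strict, so a
saccade exactly at a bound is excluded — ties at a continuous boundary are
measure-zero in practice, but the convention is fixed and tested.

Direction is the sign of the horizontal end-minus-start position (the task
is horizontal; vertical drift is ignored). Prosaccades are analysed only
when the primary saccade is toward the target; by default a wrong-way
prosaccade invalidates the trial (`prosaccade_rule = "discard"`). The
alternative reading — search the trial for the first *toward-target* valid
saccade — is implemented behind `prosaccade_rule = "first_toward"`. We
default to discarding because it never silently substitutes a corrective
saccade for the primary response.

The participant-level outlier filter removes trials deviating more than
2.5 sample SDs from the participant's cell mean (subject × condition ×
task). Prosaccades are screened jointly on latency, peak velocity,
amplitude, and a within-participant peak-velocity residual; antisaccades on
latency only. Two fixed choices: the filter is *single-pass* (means and SDs
are not recomputed after removals, avoiding an ill-defined iteration), and
the residuals used for screening are computed within the participant's own
cell, while the analysis-grade residuals are recomputed afterwards by
`fit_velocity_residuals()` on the filtered set — a documented double
computation. Cells with fewer than three valid trials are flagged and left
unfiltered rather than filtered on a meaningless SD.

Antisaccade error rate is the proportion of incorrectly directed
antisaccades among *completed* trials (the task's 24 minus all removals),
so gate failures and outlier removals shrink the denominator.

## Velocity residuals and profiles

The amplitude dependence of peak velocity is removed by OLS of velocity on
amplitude; the residuals are the amplitude-corrected velocity measure. The
phrase "regressing amplitude against velocity" is directionally ambiguous
in common usage; since the product of interest is a *velocity* residual,
velocity is the response. The default regression scope pools all prosaccades
of the comparison set, making residuals comparable across conditions (a
constant velocity shift moves the intercept, leaving condition contrasts of
residuals invariant — a tested property); per-participant scope is available
and is what the outlier filter uses.

Time-normalized profiles map each saccade onto $[0, 1]$, partition samples
into 10 equal bins (half-open, last closed), and average velocity and
cumulative amplitude (trapezoidal integral over real time) per bin.
Saccades with fewer than 10 samples are linearly resampled to 100 points
first.

## Pupil preprocessing

The chain per session: (1) partition into 15 s windows and drop windows
with strictly more than 15 % of samples missing, assessed on the **raw**
validity mask; (2) extend each invalid run by 100 ms on both sides;
(3) linearly interpolate invalid samples (constant extension at the trace
ends); (4) smooth with a unit-sum Hann kernel, 200 ms by default, edges by
reflection; (5) z-score, drop samples beyond ±3 SD, and average the
survivors within kept windows.

Choices the convention leaves open, fixed here: window QC counts
*pre-padding* missingness (padding is a conservative treatment of blink
edges, not additional data loss); the ±3 SD clip applies to the smoothed,
z-scored signal; the Hann width (unstated in common protocols) defaults to
200 ms and is exposed as a parameter; reflection and constant extension
were chosen for endpoint stability over zero-padding.

One subtlety matters for crossover designs: z-scoring each session against
itself forces every session's mean toward zero, which would erase any
between-condition diameter difference. `zscore_clip_mean()` therefore
accepts an external baseline (`center`, `scale`), and the cohort driver
`process_pupil_cohort()` defaults to a *subject-level* baseline pooled
across that subject's sessions, so a drug-induced diameter shift survives
normalization while between-subject scale differences are still removed.
Per-session normalization remains available (`normalize = "session"`) and
is the single-trace default, under which the full chain is exactly
invariant to affine rescaling of the input (a tested property).

## The synthetic cohort generator

The generator (`gen_cohort()`) exists so every downstream stage can be
tested against known ground truth. Its defaults encode the target study
design: 19 patients in a double-blind crossover (drug and placebo sessions,
visit order block-randomized), 25 single-visit controls; per task block
24 trials with eccentricities ±3°, ±5°, ±7° balanced and randomized;
central fixation 800–1200 ms, a 200 ms gap, 500 Hz sampling; 3 min resting
pupil recordings.

Latent subject parameters and their population defaults:

| parameter | default | why |
|---|---|---|
| $V$ (controls) | 130 ± 10 deg·s⁻¹·deg⁻¹ᐟ² | mid-range normative main-sequence coefficient for 2–8° saccades |
| patient $V$ offset | +10 | places the untreated patient main sequence above the normative curve; the drug's `v_shift = −10` normalizes it |
| latency | 90 ms + lognormal(log 110, 0.35) | shifted lognormal: right-skewed latencies with a hard 90 ms floor matching the anticipation gate; median ≈ 200 ms |
| gain | 0.9 ± 0.05 | mild hypometria typical of older and patient cohorts |
| amplitude / velocity noise | CV 5 % / 10 % | trial-to-trial kinematic variability |
| error propensity | logit −1.4 ± 0.5 | baseline antisaccade error rates around 15–25 % |
| urgency coupling | 0.8 | fast responses are more error prone (speed–accuracy trade-off) |
| blink rate | 15 min⁻¹ | typical resting blink contamination |
| drug offsets | −15 ms latency, −10 V, +0.6 error logit, +150 a.u. pupil | faster saccades, normalized main sequence, more antisaccade errors, dilated pupil on drug |

No per-condition latency or velocity means are available as calibration
targets from summary tables alone, so these defaults are order-of-magnitude
plausible values fixed once, not fitted.

Mechanisms, and what they do and do not emulate:

- **Kinematics.** Every saccade lies on the subject's square-root main
  sequence up to multiplicative noise; with all noise at zero the
  generator's saccades sit on $y = V\sqrt{x}$ to machine precision.
- **Velocity traces** are raised cosines — symmetric acceleration and
  deceleration about the peak — with the trace's peak equal to the drawn
  peak velocity. Duration is derived as $D = 2A/v_p$, the unique duration
  for which a raised cosine with that peak integrates exactly to the
  amplitude $A$; this keeps the event table and the sample trace mutually
  consistent (both properties are tested) and yields durations in the same
  30–45 ms range as the classic linear duration–amplitude rule. Real
  saccades are mildly asymmetric; skewness is deliberately not modelled.
- **Antisaccade errors** follow a logistic model on the trial's latency
  standardized against the *population* latency distribution:
  $p_{\mathrm{err}} = \mathrm{logit}^{-1}(\beta_0 + c\,(-z) + \delta)$.
  Population (not per-subject) standardization makes habitually fast
  subjects more error prone — producing the negative across-subject
  correlation between prosaccade latency and antisaccade error rate — while
  fast trials remain more error prone within subject. This is the simplest
  mechanism reproducing both couplings; it is not an accumulator race
  model and makes no claim about underlying dynamics.
- **Pupil traces** are baseline + slow sinusoidal drift + white noise, with
  Poisson blinks zeroing 50–200 ms runs. A small fraction of trials
  (5 %) carries an early sub-degree distractor saccade so the validity
  gates are exercised. Not modelled: fixational eye movements, square-wave
  jerks, vertical saccades, pupil foreshortening, event-locked pupil
  responses.

Determinism: one global integer seed; per-subject and per-stage substreams
are derived by a stable polynomial hash of the subject id and stage label,
so identical configs give byte-identical cohorts regardless of call order,
and the user's RNG state is never disturbed.

Because the generator shares the square-root law with the fitting code by
design, parameter recovery tests validate the estimation machinery (bias,
coverage, filters, bookkeeping) — they cannot validate the model's adequacy
for real eye-tracking data, where detection noise, corrective saccades and
asymmetric profiles add structure the generator omits.

## Bayesian and frequentist inference

Summary-statistic t-tests implement the standard pooled-variance and
Welch forms. The JZS Bayes factor places a Cauchy prior (scale
$r = \sqrt{2}/2$, the default of the package family this convention comes
from) on the standardized effect; BF₁₀ is the ratio of the marginal
likelihood of the observed $t$ under that prior to its value at zero
effect. One-sample designs use $N = n$, $\nu = n-1$; two-sample designs use
the effective $N = n_1 n_2/(n_1+n_2)$, $\nu = n_1+n_2-2$.

Numerics: the Cauchy prior is integrated through its normal scale-mixture
representation ($g \sim$ inverse-gamma(½, ½)), with the substitution
$u = \log g$ so the integrand is smooth on $(-\infty, \infty)$, evaluated
in log space against the null likelihood's peak to avoid under/overflow,
and integrated adaptively (`stats::integrate`, relative tolerance 1e−8);
the reported `error` field propagates the quadrature's error estimate and
stays below 1e−4 relative in the tested range. Tests cross-check this route
against an independent dense-trapezoid integral of the non-central t
likelihood against the Cauchy density.

When reconstructing Bayes factors from `(n, mean, SD)` summaries, the
*pooled* t is used (it is the sufficient statistic the JZS t Bayes factor
is derived under), while printed frequentist p-values from such tables are
typically Welch — `t_from_summary()` offers both, and the two can disagree
at unequal variances; `bf_from_summaries()` documents this choice.

Pearson correlations use `stats::cor.test`; FDR correction is
Benjamini–Hochberg step-up within each *declared family* of comparisons,
so unrelated measure families are not pooled into one correction.

## Problem sizes and runtime choices

Test and example workloads are scaled to keep a full suite run fast on one
CPU: simulated validation cohorts use 4 patients + 5 controls with 16–30 s
pupil traces; parameter-recovery studies use 200 single-subject cohorts of
300 saccades with 1000 bootstrap resamples; null calibration of the Welch
test uses 2000 simulated datasets at the study's 19/25 group sizes. The
full-size default cohort (19 + 25 subjects, 3 min pupil traces, ~5.7 M
pupil samples) runs through `run_all()` in well under two minutes.

## Known limitations

- Saccade detection is upstream: the pipeline consumes event tables from a
  tracker's detector and cannot compensate for detection errors.
- Trial-level $\Delta$ tests ignore within-subject correlation; mixed
  models on the exported tables are the remedy and are out of scope here.
- The square-root law is a small-amplitude approximation; above ~15° a
  saturating form would be needed (the 10° gate keeps fits in range).
- The bootstrap interval is a percentile interval; no BCa correction.
- Pupil diameter stays in arbitrary tracker units; no mm calibration or
  foreshortening correction is attempted.
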