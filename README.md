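# saccadeflow

Saccade kinematics and resting pupillometry for oculomotor pharmacology
studies, built around the designs used to probe noradrenergic modulation in
Parkinson's disease: a placebo-controlled crossover in patients plus a
single-visit normative control group, with prosaccade and antisaccade task
blocks recorded on a 500 Hz eye tracker.

Oculomotor read-outs are attractive in movement disorders because they index
decision processes without limb-motor confounds. The package implements the
analysis chain such studies need:

- **Resting pupil diameter** — 15 s window quality control (> 15 % missing
  dropped), 100 ms blink padding, linear interpolation, Hann-window
  smoothing, z-scoring with ± 3 SD sample clipping, and a mean over
  surviving windows per session.
- **Trial parsing** — primary-saccade selection (first saccade with
  amplitude strictly between 1.5° and 10° and latency strictly between
  90 ms and 2500 ms), direction classification, a single-pass ± 2.5 SD
  participant-level outlier filter (latency, peak velocity, amplitude and
  peak-velocity residual for prosaccades; latency for antisaccades), and
  antisaccade error rates over completed trials.
- **Kinematics** — peak-velocity residuals (OLS of velocity on amplitude)
  and 10-bin time-normalized velocity/amplitude profiles.
- **Main sequence** — the square-root model `y = V √x` (peak velocity `y`,
  absolute amplitude `x`), fitted in closed form (`V = Σ y√x / Σ x`),
  bootstrapped (1000 case resamples, median and 95 % percentile interval),
  and a normative deviation statistic: Δ peak velocity
  `Δᵢ = yᵢ − V_ctrl √xᵢ` against a frozen control-group curve, tested
  against zero with a trial-level t-test and a JZS Bayes factor.
- **Inference** — pooled and Welch t-tests from `(n, mean, SD)` summaries,
  default Jeffreys–Zellner–Siow Bayes factors (Cauchy prior, scale √2⁄2)
  for one- and two-sample designs via adaptive quadrature, and Pearson
  correlations with Benjamini–Hochberg FDR correction within declared
  families.
- **Synthetic cohorts** — a seeded generator producing the full crossover
  design (trials, saccade events, raised-cosine velocity traces,
  blink-contaminated pupil traces) with known ground-truth parameters, so
  the entire pipeline is testable without any eye-tracking data.

## Worked example

Simulate a small crossover cohort and run the whole chain:

```r
library(saccadeflow)

gen <- generator_config(seed = 11, n_patients = 4, n_controls = 5,
                        pupil_duration_s = 30)
cfg <- run_config(out_dir = "demo_out", generator = gen, n_boot = 200)
res <- run_all(cfg)
writeLines(readLines("demo_out/report.txt"))
```

```
saccadeflow pipeline report
seed: 11
events: 654 rows; trials: 624; valid primaries: 609; removed: 15

Main-sequence fits (V, deg/s per sqrt(deg)):
  control      V =  127.94  [124.83, 130.75]  n = 116
  placebo      V =  142.21  [138.84, 145.65]  n = 93
  atomoxetine  V =  130.68  [127.38, 134.02]  n = 94

Delta peak velocity vs control curve:
  placebo      mean =  29.11 deg/s, t(92) = 8.12, p = 2.054e-12, BF10 = 3.96e+09
  atomoxetine  mean =   5.37 deg/s, t(93) = 1.59, p = 0.1154, BF10 = 0.383

Pupil (paired, drug - placebo): mean dz = 1.820, t(3) = 201.97, p = 2.676e-07, BF10 = 7.67e+03
```

Reading the report: the patients' placebo main sequence sits above the
control curve (positive Δ peak velocity, decisively non-zero), while on the
drug the coefficient returns to the normative value (Δ indistinguishable
from zero) — the generator's built-in ground truth, recovered by the
pipeline. The paired pupil contrast shows the expected diameter increase on
the drug. Outputs land in `demo_out/` as plain TSV/JSON (`events.tsv`,
`primary_saccades.tsv`, `removal_log.tsv`, `task_summary.tsv`,
`residuals.tsv`, `profiles.tsv`, `deltas.tsv`, `mainseq_fit.json`,
`pupil_summary.tsv`) plus a `manifest.json` with checksums and row counts;
reruns with the same config are byte-identical.

Summary-statistic inference works stand-alone:

```r
bf_from_summaries(group_summary(19, 67.11, 7.05),
                  group_summary(25, 65.40, 5.42))
#> JZS BF10 (two-sample, r = 0.707): 0.4179  [t = 0.910, df = 42.0]
jzs_bf_t(3.31, n1 = 372)
#> JZS BF10 (one-sample, r = 0.707): 12.35  [t = 3.310, df = 371.0]
```

A thin command-line wrapper is installed as `exec/saccadeflow` with
subcommands `simulate | pupil | parse | mainseq | stats | run-all`.

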