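# divetrack

Three-dimensional behavioral phenotyping of zebrafish in the novel tank
diving test — and an accounting of what a single-camera 2D analysis would
get wrong.

## The problem

In the novel tank diving test, an adult zebrafish released into an
unfamiliar tank dives to the bottom and gradually explores upward;
swimming speed, erratic turning, freezing, wall hugging and vertical
position together index anxiety, and drugs such as citalopram and
ethanol modulate their time course over the 6-minute trial. Most labs
score the assay from one camera — overhead (x–y) or frontal (x–z) — even
though the behavior is three-dimensional. Every 2D projection shortens
swim paths and hides one spatial axis, so group comparisons run on a
projection can disagree with those supported by the full 3D trajectory.

`divetrack` is for behavioral pharmacologists and computational
ethologists who want to (a) reconstruct 3D tracks from two unsynchronized
camera views, (b) score the standard nine-measure novel-tank ethogram
identically in 3D and in either projection, (c) run the conventional
statistical battery, and (d) count how many **false positives** (a
contrast significant in 2D but not in 3D) and **false negatives** (missed
in 2D, significant in 3D) each single-view analysis would have produced.

## What it implements

* **Two-view synchronization and fusion.** Both cameras observe the
  position along the tank's length (x). The integer frame shift
  minimizing the mean squared difference of the two x series is selected
  (`estimate_lag()`); fused frames take x as the mean of the views, y
  from the top view, z from the front view (`fuse()`), with short-gap
  linear repair (`fill_gaps()`).
* **The nine-measure ethogram per 1-minute bin** (`compute_ethogram()`):
  average and 90th-percentile-peak speed, acceleration and angular speed
  (first-order forward differences); freezing (< 2 cm displacement over a
  rolling 2 s window); wall following (within 3 cm of any boundary
  observable in the view); time in the top half of the water column
  (z > 6.5 cm; not scorable from the top view).
* **Statistics** (`pca_varimax()`, `splitplot_anova()`,
  `dunnett_contrasts()`, `posthoc_dunnett()`,
  `residual_diagnostics()`): correlation-matrix PCA with eigenvalue > 1
  retention and Kaiser-normalized varimax rotation; split-plot
  repeated-measures ANOVA (between: condition, sex; within: time bin,
  scoring view) via `aov` error strata; Dunnett many-to-one contrasts
  (condition vs control, each minute vs the first) with adjusted p from
  the equicoordinate multivariate t distribution.
* **The findings ledger** (`view_contrast_battery()`,
  `matched_contrasts()`, `classify_findings()`, `ledger_table()`):
  per-measure, per-2D-view false positive / false negative counts against
  the 3D ground truth.
* **A stochastic swim simulator** (`simulate_trajectory()`,
  `simulate_cohort()`, `degrade()`): mean-reverting speed, heading
  diffusion, Markov freezing, wall attraction, depth preference, per-bin
  habituation multipliers, plus camera-artifact injection (lag, dropout,
  noise) — reproducing the 7-group, 16-per-group (minus dropouts),
  sex-balanced study design for end-to-end validation.

## Worked example

Simulate one fish, emulate the two-camera acquisition with an unknown
12-frame offset plus tracking noise, re-synchronize, reconstruct, and
score the ethogram:

```r
library(divetrack)

tank <- tank_geometry()            # 29 x 8.5 cm, 13 cm water
fish <- simulate_trajectory(behavior_params(depth_bias = 4), tank, seed = 42)

top   <- project(fish, "top")
front <- degrade(project(fish, "front"), lag_frames = 12,
                 dropout_prob = 0.002, noise_sd = 0.05, seed = 7)

(sync <- estimate_lag(top, front))
#> Sync: lag 12 frames (ok), cost 0.002564 cm^2 over 10774 frames

rec <- fill_gaps(fuse(top, front, sync))
rec
#> 3D trajectory 'subject': 10788 frames at 30 Hz (0 gap frames)

e <- compute_ethogram(rec, tank)
round(e[, c("bin", "avg_speed", "avg_ang_speed", "freezing_frac",
            "wall_frac", "top_half_frac")], 3)
#>   bin avg_speed avg_ang_speed freezing_frac wall_frac top_half_frac
#> 1   1     8.234        28.440         0.031     0.909         0.028
#> 2   2     7.600        33.299         0.112     0.892         0.004
#> 3   3     7.820        31.006         0.056     0.832         0.000
#> 4   4     8.755        27.807         0.033     0.859         0.003
#> 5   5     8.644        27.429         0.002     0.836         0.016
#> 6   6     8.579        26.178         0.005     0.819         0.000
```

The injected 12-frame camera offset is recovered exactly; the
reconstructed track matches the original on the overlap to within the
injected noise. Reading the measures: this fish swims ~8 cm/s, freezes
briefly in minute 2, spends >80 % of its time within 3 cm of an
observable boundary (with a 29 × 8.5 cm footprint most of the tank lies
in the 3 cm wall zone), and stays almost entirely in the bottom half —
the bottom-dwelling profile expected of an anxious fish with a 4 cm
preferred depth.

A full cohort pipeline — simulate, reconstruct, score in all three
views, PCA + split-plot ANOVA + Dunnett contrasts, findings ledger —
runs from one configuration:

```r
run_pipeline(run_config(out_dir = "demo-run", master_seed = 1,
                        compound = "citalopram", n_per_group = 4))
```

writing `metadata.csv`, `sync_report.csv`, `ethogram.csv`,
`pca_table.csv`, `anova_components.csv`, `contrasts_components.csv`,
`significance_matrix.csv`, `findings_ledger.csv`, `ledger_table.csv` and
a checksummed `manifest.csv`. A thin CLI over the same functions is in
`inst/scripts/divetrack-cli.R`.

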