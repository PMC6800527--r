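---
title: "Methods: 3D novel-tank phenotyping and the 2D-vs-3D findings ledger"
author: "divetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D novel-tank phenotyping and the 2D-vs-3D findings ledger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divetrack)
```

## The scientific problem

Adult zebrafish released into an unfamiliar tank first dive toward the
bottom and only gradually explore upward; how quickly they do so, how
erratically they swim, how much they freeze, and how closely they hug the
walls together index anxiety. Most laboratories score these behaviors from
a single camera — overhead (x–y) or frontal (x–z) — even though the fish
moves in three dimensions. A 2D projection necessarily shortens every swim
path and hides one spatial axis entirely, so statistical conclusions drawn
from a single view can differ from those supported by the full 3D
trajectory. `divetrack` implements the complete analysis chain needed to
quantify that risk: two-view synchronization and 3D fusion, a nine-measure
ethogram scored identically in 3D and in either projection, the PCA and
split-plot ANOVA battery used for drug phenotyping, and a ledger that
counts, per measure and per 2D view, the false positive and false negative
findings relative to 3D ground truth.

Because no raw trajectories are publicly deposited for this assay, the
package ships a stochastic swim simulator that reproduces the study
design: seven groups (vehicle; citalopram 30, 50, 100 mg/L; ethanol 0.25,
0.50, 1.00 %), sixteen subjects per group minus the recorded dropouts
(15, 14 and 15 in the citalopram-100, ethanol-0.25 and ethanol-1.00
groups), sex-balanced, 6-minute trials at 30 frames/s in a
29 × 8.5 cm tank with 13 cm of water. Every validation result in the test
suite and the acceptance script is computed on cohorts drawn from this
generator.

## Coordinate conventions and tank geometry

All positions are in cm, with the origin at one bottom corner of the
tank: x along the 29 cm length (the axis both cameras share), y across
the 8.5 cm width (invisible to the front camera), z upward through the
13 cm water column (invisible to the top camera). This convention makes
every spatial measure a pure threshold comparison: the top half of the
water column is z > 6.5 cm, and wall following is a distance-to-boundary
test with a 3 cm margin. `tank_geometry()` carries these thresholds, and
its validity rules keep the top-half threshold tied to half the water
depth.

One geometric fact worth stating explicitly: the tank's centerline lies
4.25 cm from each long wall, which is *outside* the 3 cm wall margin, so
a fish cruising the midline is not wall-following; with this tank the
wall zone nonetheless covers most of the floor plan, which is why
wall-following fractions run high in all views.

## The trajectory model and kinematics

Tracks are uniformly sampled position series; tracking dropouts are
explicit gap frames (`NA` rows) on the fixed 1/30 s grid, never silently
deleted, so that frame indices remain comparable across views.
Differentiation is first-order and forward: speed is the norm of the
forward position difference divided by the frame interval, acceleration
the norm of the forward velocity difference, and angular speed the angle
between successive velocity vectors divided by the frame interval
(rad/s).

Three numerical choices here were genuinely open:

* **Angular speed as heading-change rate, not curvature.** The two
  coincide for smooth paths (curvature times speed equals the heading
  rate), but the heading rate is well defined frame-by-frame and does not
  blow up at low speed. Heading is still undefined at near-zero velocity,
  so angular-speed frames with either flanking speed below
  `speed_floor = 0.5` cm/s are marked invalid — this also removes
  freezing bouts from the angular-speed averages, where they would
  otherwise contribute pure noise.
* **No smoothing by default.** Whether the original pipeline smoothed
  positions before differencing is not stated; an optional boxcar
  (`smooth_window`) exists but is off, and the closed-form tests (line,
  circle at 30 and 300 Hz) document the first-order truncation error of
  the raw scheme.
* **No interpolation inside kinematics.** Frames adjacent to gaps are
  invalidated instead; short-gap repair is a separate, flagged step
  (`fill_gaps()`, linear, capped at 5 frames by default) used only during
  reconstruction.

## Synchronization and 3D fusion

The two cameras start asynchronously; both, however, observe the x
coordinate. `estimate_lag()` shifts the two x series against each other
over integer frame offsets (default search half-width 90 frames, i.e.
3 s) and picks the shift minimizing the mean squared difference over the
valid overlap, excluding gap frames pairwise. Mean squared error is the
natural cost under Gaussian tracking noise; ties break toward the
smallest absolute lag. Sub-frame interpolation is deliberately not
attempted — the cameras share a nominal 30 fps clock and the remaining
offset is an integer start-frame difference. A constant x series (a fish
that never moves along the length of the tank) makes the alignment
undetermined; the estimator then reports lag 0 with a `degenerate`
status rather than failing.

`fuse()` assembles, for every overlapping frame, x as the average of the
two views (symmetric, variance-halving; the per-frame |x(top) − x(front)|
disagreement is kept as a quality series), y from the top view and z from
the front view. Frames missing in either view become gaps. The
end-to-end property — project a trajectory to both views, offset one
stream by any lag in ±30 frames, re-estimate, fuse — reproduces the
source positions exactly in the noiseless case, and the test suite
verifies exact integer-lag recovery at 0.1 cm noise in at least 95 of 100
replicates.

## The nine-measure ethogram

Per subject, per scoring view, per 1-minute bin (six bins over the
trial), `compute_ethogram()` scores:

1–6. average and *peak* speed, acceleration, angular speed — the peak
aggregate is the time-average of the values strictly above the series'
own 90th percentile (linear-interpolation percentile), computed **within
each bin**, since the subject × bin cell is the observational unit of the
downstream ANOVA;

7. **freezing**: the fraction of frames from which the fish moves less
than 2 cm over the trailing 2 s window. "Moved" is interpreted as the
maximum displacement from the window's starting position — the strictest
of the candidate readings (net displacement, path length, diameter);
windows at the end of the track use the available remainder;

8. **wall following**: the fraction of frames within 3 cm of a boundary
*observable in that view* — all four side walls plus the bottom in 3D,
the side walls only from the top (the bottom is invisible from above),
the two short walls plus the bottom from the front (the long walls are
invisible head-on). This per-view margin set is what makes the front
view structurally underestimate thigmotaxis;

9. **time in the top half**: the fraction of frames with z above half
the water depth — not scorable from the top view, where it is carried as
a not-available marker (`NA`), never an error, so the downstream ledger
can distinguish "not applicable" from "not significant".

The identical dimension-generic code path scores 3D trajectories and 2D
projections, which guarantees that 2D-vs-3D differences reflect the
projection, not implementation divergence. Every measure is checked
against an independent, deliberately unvectorized reference
implementation to 10⁻⁹ on random tracks.

## The swim simulator

No generative model is specified by the assay itself, so the simulator is
the minimal stochastic model that spans all nine measures, with one
independently controllable knob per behavior:

* swimming speed: reflected Ornstein–Uhlenbeck process
  (`mean_speed` ≈ 7 cm/s, relaxation 1 /s, diffusion 3 cm s^−1.5);
* heading: Brownian rotation scaled by `turn_rate_sd` (erratic
  movement), plus optional steering toward the nearest side wall at rate
  `wall_attraction` (thigmotaxis);
* depth: relaxation toward `depth_bias` with vertical noise (geotaxis;
  stationary spread ≈ 1 cm with the defaults);
* freezing: a two-state continuous-time Markov chain
  (`freeze_on_rate`, `freeze_off_rate`); the fish holds position while
  frozen, and state occupancy converges to on/(on + off);
* habituation: every parameter can be scaled per 1-minute bin through a
  multiplier schedule — the default study design lets locomotion decline
  and the preferred depth rise across the session, the canonical
  novel-tank time course.

Walls are handled by soft reflection plus clamping rather than hard
specular bounces, so no artificial high-curvature events contaminate the
angular-speed measures; every simulated position lies inside the tank, a
hard invariant of the test suite. Per-subject seeds derive from the
cohort's master seed by a stable integer hash of the subject index, so
cohorts are bit-reproducible regardless of evaluation order.

Drug-group parameterizations in `default_cohort_design()` are qualitative
conventions, not estimates — the assay's published results report test
statistics, not effect sizes usable as simulation ground truth. The
defaults encode the directions the anxiety-pharmacology literature
agrees on (citalopram: dose-dependent rise in the water column, sedation
at the highest dose; ethanol: anxiogenic at the middle dose, sedative at
the highest), with magnitudes chosen once so that parameter-recovery
simulations succeed with modest replicate counts on one CPU. What passing
tests show is that the *analysis chain* recovers programmed effects of
realistic size and direction; they cannot certify behavior on real video
tracking, which has artifacts (identity swaps, reflections, refraction at
the surface) the generator deliberately does not model.

## The statistical battery

**PCA.** The nine measures mix units (cm/s, rad/s, proportions), so the
PCA operates on the correlation matrix — equivalently on standardized
columns; this is also the only reading under which the reported
eigenvalues can sum to the number of measures. Observations are
subject × bin rows (time-resolved scores are needed as ANOVA responses).
Components with eigenvalue > 1 are retained and varimax-rotated with
Kaiser normalization. The rotation is implemented as classical pairwise
Jacobi sweeps with the closed-form optimal planar angle, tolerance 10⁻⁶,
at most 1000 sweeps; the criterion is non-decreasing across sweeps and
the result is checked against `stats::varimax` in the test suite.
Component signs follow the largest-loading-positive convention; scores
use the regression method. On block-correlated data mirroring the
locomotion / behavioral-anxiety / positional-anxiety structure, exactly
three components are retained and each loads above 0.7 on its own block
in ≥ 95 % of replicates.

**Split-plot ANOVA.** Fitted with `stats::aov` and an
`Error(subject/(within factors))` term — the classical univariate
split-plot decomposition with sequential sums of squares. Between factors
(condition, sex) are tested against subjects-within-cells; each within
factor (bin, view) and its interactions with between factors against the
corresponding factor × subject stratum. For the citalopram-arm design (63
subjects in 4 × 2 between cells, 6 bins, 3 views) the engine reproduces
the design-determined df pairs exactly: condition (3, 55), time (5, 275),
time × condition (15, 275), view (2, 110), time × view (10, 550). For the
ethanol arm the stated group sizes (16 + 14 + 16 + 15 = 61 subjects)
yield (3, 53) and (2, 106); published ethanol statistics imply 60
analyzed subjects, a one-subject bookkeeping discrepancy we reproduce
from whatever cohort is supplied rather than force. No sphericity
correction is applied (none is part of the original analysis);
`residual_diagnostics()` supports the visual normality check with
per-stratum skewness, excess kurtosis and Q-Q data, and flags gross
violations without auto-rejecting.

**Dunnett contrasts.** The two post hoc families are each condition
against the control, and each time bin against the first minute (overall
or within condition/view when the corresponding interaction warrants).
Adjusted p-values come from the equicoordinate multivariate t
distribution with the exact contrast correlation matrix (equicorrelation
1/2 in the balanced case, √(nᵢnⱼ/((nᵢ+n₀)(nⱼ+n₀))) when group sizes
differ), evaluated with `mvtnorm::pmvt` under a fixed internal seed so
results are reproducible. With one comparison the adjustment reduces to
the ordinary two-sided t-test; the suite checks agreement with a 10⁶-draw
Monte-Carlo oracle to 0.002 and familywise error control over 2000 null
simulations. Simulation-based calibration of the full ANOVA uses 500 null
cohorts at 8 subjects per group — large enough for the binomial 95 %
interval around the nominal 0.05 to be ±0.019, small enough to run on one
CPU in seconds.

## The findings ledger

For every measure and every contrast in the shared universe, run in all
three views at α = 0.05, the 3D result is treated as ground truth: a
contrast significant in a 2D view but not in 3D is a **false positive**,
one missed in 2D but significant in 3D a **false negative**. Cells where
a measure is unscorable in a view (top half from the top view) are
not-applicable and excluded from both counts. The contrast universe is
the union of the Dunnett families actually run; by default a family
enters only when its omnibus ANOVA term is significant in at least one
view (configurable to always-run), and the universe definition is logged
because the countable universe behind any published FP/FN totals is not
reconstructible from text alone — which is also why empirical ledger
counts are validated structurally (definitions, exclusivity, symmetry,
zero-ledger under identical inputs) rather than against printed totals.

## Problem sizes and reproducibility

The validation suite uses: one 63-subject citalopram-arm cohort (full
6-minute trials) for the df and projection-inequality checks; 61
noiseless plus 100 noisy lag-recovery replicates on 60 s tracks; 50
random 500-frame tracks for oracle equivalence; 500 null cohorts (8
subjects/group) for ANOVA calibration and 2000 for Dunnett familywise
error; 20 replicate two-group cohorts for end-to-end effect recovery; and
100 replicates for PCA structure recovery. These sizes were chosen so the
whole battery runs on a single CPU in minutes while keeping Monte-Carlo
error well inside each criterion's margin. `scripts/acceptance.R` re-runs
the entire battery from scratch under a caller-supplied seed.

## Known limitations

* The simulator does not model refraction at the water surface, lens
  distortion, multi-fish occlusion, or tracking identity errors; lag,
  dropout and Gaussian jitter are the only acquisition artifacts
  emulated.
* Freezing's rolling window labels the last fraction of a second of any
  track frozen by construction (the remainder window is short); at 6-min
  trials this end effect is negligible but it is visible on very short
  synthetic tracks.
* Sequential (Type I) sums of squares mirror the classical fit; with the
  mild group-size imbalance (14–16) effect tests are order-dependent in
  principle, while the df — the reproducible design quantities — are not.
* The between-cell sex balance is exact only for even group sizes;
  dropout groups alternate sexes (8/7).
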