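# transsacc

Stimulus synthesis and analysis tools for studying **perceptual grouping of
object contours across saccades** — for visual psychophysicists building
preview/test paradigms in which spatially separate local elements must be
grouped into a closed contour, and for anyone who needs the accompanying
eye-movement and reaction-time analysis pipeline.

## What it does

**Stimulus synthesis.** Each display latently contains two closed radial
frequency pattern (RFP) contours,

r(θ) = r₀ + Σᵢ Aᵢ sin(fᵢ θ + φᵢ),  r₀ = 1°, fᵢ ∈ {2,3,4}, Aᵢ ∈ [0.03, 0.1]°,

a first random contour plus a partner selected from 100 candidates by
compatibility (inter-intersection segment length, radial separation,
crossing angles). Local elements are placed exactly on both contours with
arc-length jitter (consecutive spacings within 58–142% of the average
element distance, ≥ 50% clearance from contour intersections), the
background is filled until a rank-sum test on nearest-neighbour distances
shows no proximity cue (p > 0.3), and a target square is positioned at
0.75–1.35° eccentricity — inside both contours in 25% of displays, outside
both in 25%, mixed in 50%. Displays render as Gaussian-blob previews
(luminance grouping cue) and Gabor test images (collinearity grouping cue)
with identical element positions, plus PNG/JSON export.

**Behavioral simulation.** `simulate_experiment()` generates trial tables
(saccadic latencies as shifted lognormals, 2D landing distributions, manual
RTs with condition effects and a landing-error slope, additional-saccade
counts, near-ceiling accuracy) so the analysis pipeline is testable without
the unpublished eye-tracking data it was designed for.

**Analysis.** Trial censoring (landing > 1.5°, saccade duration > 85 ms,
> 2 additional saccades, two additional saccades with final fixation
≥ 240 ms, plus data-driven re-derivation of that cutoff), discrete-time
survival/hazard functions (5/15 ms bins, five-bin smoothed hazard),
subject-median normalization, landing-adjusted log-RT condition contrasts
(repeated-measures, error = subject × condition), analysis of variance of
variance for landing spread, within-subject logistic accuracy models,
landing iso-frequency maps (10-px bins, 90% mass), and coarse-shape
(minimum-bounding-rectangle) control analyses.

## Worked example

```r
library(transsacc)
library(dplyr)

trials <- simulate_experiment(sim_config(), seed = 42)
kept   <- censor_trials(trials)
censor_report(kept)
#> <censor_report: 3500 in, 2978 retained (85.09%); removed: landing=18,
#>  duration=1, extra_saccades=94, slow_second_fixation=409>

analysis <- kept |>
  filter(correct, rt_ms <= 1500) |>
  adjust_rt_for_landing() |>
  condition_contrasts()
tidy(analysis)
#> # A tibble: 5 x 9
#>   contrast               estimate     se       F   df1   df2        p diff_ms se_ms
#>   <chr>                     <dbl>  <dbl>   <dbl> <int> <int>    <dbl>   <dbl> <dbl>
#> 1 neutral_vs_object       0.00709 0.0106 0.447       1    24 0.510      4.30   6.43
#> 2 uniform_vs_random      -0.00137 0.0164 0.00699     1    24 0.934     -0.836  9.96
#> 3 same_vs_different      -0.0686  0.0164 17.4        1    24 0.000340 -41.6    9.96
#> 4 same_vs_localized      -0.0250  0.0164 2.32        1    24 0.140    -14.9    9.96
#> 5 different_vs_localized  0.0435  0.0164 7.01        1    24 0.0141    26.7    9.96
```

The `estimate` column is the contrast of adjusted log reaction times (cell
means over subjects), each tested on F(1, 24) — five conditions by seven
subjects; `diff_ms` back-transforms it to a millisecond difference of
geometric means. In this run the simulated same-contour preview speeds
grouping by ≈15 ms and the mismatching preview costs ≈27 ms relative to the
localized baseline (a 42 ms same−different gap, against configured effects of
−16/+19 ms), while uniform and random previews do not differ — the pattern
the pipeline is designed to detect.

Survival/hazard descriptions of the same data:

```r
trials |>
  normalize_medians(saccade_latency_ms, subject_id) |>
  survival_hazard(saccade_latency_ms, bin_ms = 5, condition = condition) |>
  autoplot()
```

Stimulus generation:

```r
batch <- generate_stimulus_batch(n_sets = 8, seed = 7)
imgs  <- render_stimulus_set(batch[[1]])
write_display_png(imgs$postsac1, "set001_postsac1.png")
```

A command-line wrapper for batch generation, simulation and censoring ships
in `inst/scripts/transsacc-cli.R`.

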