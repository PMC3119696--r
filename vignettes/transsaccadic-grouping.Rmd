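---
title: "Stimulus synthesis and analysis for transsaccadic contour grouping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus synthesis and analysis for transsaccadic contour grouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(transsacc)
library(dplyr)
```

## The problem

When observers scan a scene, every saccade target has already been glimpsed
peripherally before the eyes land on it. A central question in transsaccadic
vision is what level of description survives the eye movement: raw image
detail, or an intermediate representation of perceptual organization — which
elements group together into an object contour. `transsacc` provides the full
experimental machinery for studying this with perceptual-grouping displays:

1. **Stimulus synthesis** — element displays that latently contain two closed
   contours, where grouping can be switched on and off via element luminance
   (previews) or element orientation (test displays), without moving a single
   element.
2. **A trial simulator** — behavioral and eye-movement data with the
   statistical structure the analysis assumes, since no raw eye-tracking data
   ship with the package.
3. **The analysis pipeline** — trial censoring, discrete-time survival and
   hazard functions, landing-adjusted reaction-time contrasts, dispersion and
   accuracy analyses, and coarse-shape controls.

## Radial frequency contours

A stimulus contour is a radial frequency pattern: in polar coordinates,

$$r(\theta) = r_0 + \sum_{i=1}^{10} A_i \sin(f_i \theta + \phi_i),$$

with base radius $r_0 = 1^\circ$, frequencies $f_i$ drawn from $\{2, 3, 4\}$,
amplitudes $A_i \in [0.03, 0.1]^\circ$ and random phases. Frequencies are
integers: a frequency range of "2 to 4" must be restricted to integers
for the curve to close after one revolution ($r(0) = r(2\pi)$), which
we treat as a hard requirement; non-integer frequencies are unsupported.
Because integer-frequency sinusoids integrate to zero over a revolution, the
angular mean radius of every contour equals $r_0$ exactly — a convenient
internal check, computed by periodic (rectangle-rule) quadrature, which is
spectrally accurate for trigonometric polynomials.

```{r contour}
cntr <- generate_contour(seed = 1)
mean_radius(cntr)
```

Each display pairs a first contour with a *partner* selected from 100 fresh
random candidates. Candidates are scored on three criteria computed from
their superposition with the first contour: the minimal along-contour segment
between intersections (longer is better — room for elements), the mean radial
distance between the radius functions (larger is better — discriminable
shapes), and the deviation of crossing angles from 90° (smaller is better —
clean X-junctions). The field describes the criteria but not the selection
rule, so the combination is our design choice: each criterion is z-scored
within the candidate pool and summed with configurable weights (default
1, 1, 1), with a hard feasibility floor on the minimal segment (default
0.35°, about one element spacing) and a tie-break to the first candidate.
Partner selection and intersection geometry run in a shared polar frame;
afterwards both contours are translated together so that the *first*
contour's area centroid sits on the display center, standardizing the saccade
landing position while preserving the superposition.

## Element layout

Elements are placed exactly on each contour at equidistant arc-length
positions plus uniform arc-length jitter, constrained so that consecutive
spacings stay between 58% and 142% of the average element distance and every
element keeps at least half that distance from any contour intersection.
Two implementation points deserve note:

* The spacing band is defined relative to the *realized* average spacing
  (perimeter divided by element count), not the requested target spacing —
  with jitter disabled, all spacing ratios are exactly 1. The requested
  spacing (default 0.35°, chosen once to visually match the published example
  display; never printed in the source experiment) only determines the count.
* Jitter is resampled on constraint violation rather than clipped; clipping
  would pile spacings onto the band edges and bias the layout statistics.

The rest of the display is filled by dart-throwing: uniform candidate
positions, rejected within half an average spacing of any existing element,
until the display carries at least 20 background elements (our choice; it
prevents a trivially early stop with a near-empty background) *and* a
two-sided Wilcoxon rank-sum test comparing nearest-neighbour distances of
contour vs background elements clears p > 0.3 — the operationalization of "no
proximity cue". The original statistic behind that criterion is not
documented; the rank-sum test on nearest-neighbour distances is the most
direct reading and is flagged as a package choice, not as the original.

One background element per display is replaced by the target square, at
0.75–1.35° eccentricity, at least 0.05° clear of either contour (so the
inside/outside judgement is never ambiguous), stratified exactly across a
batch: 25% of displays inside both contours, 25% outside both, 50% mixed.
Across a batch this stratification is solved greedily with retries; sets that
cannot host a required class are regenerated.

```{r batch, eval = FALSE}
batch <- generate_stimulus_batch(n_sets = 8, seed = 7)
table(vapply(batch, function(s) s$target_class, character(1)))
```

## Rendering

Displays are normalized-luminance images on a 0.5 background, 3.8° square,
at a default 47.06 px/° (an 800-px image spanning a 17°-wide monitor). The
preview elements are Gaussian blobs (sd 0.05°) peaking at 0.77 (lit) or 0.64
(unlit). The five preview conditions differ only in which elements are lit:
all (*uniform*), a random half (*random*), a random half of the elements
within the maximal contour radius (*localized*), or exactly the elements of
one latent contour (*same*/*different*, resolved against the postsaccadic
stimulus). Test displays use even-symmetric Gabor patches (envelope sd 0.06°,
10 cycles/°): "phase 0" is implemented as cosine phase, since only the
even-symmetric patch attains the stated 0.77 peak at the element center.
Displayed-contour elements are oriented along the local contour tangent
±22.5° of uniform jitter; all other elements are oriented uniformly at
random. The target square is 7 px (≈0.15°) at the default scale: a 2-px
border at 0.75 around a 3-px core at 0.25. Overlapping profiles are summed
before clipping to [0, 1] (the original compositing rule is unstated;
summation is linear and the spacing constraints keep overlap negligible).
Images round-trip through 8-bit grayscale PNG within 1/255 per pixel.

## The trial simulator

The study's raw data are not public, so analyses are exercised on simulated
trial tables (`simulate_experiment()`). The generator is deliberately simple
and fully configurable (`sim_config()`); defaults are set once to plausible
values matching the printed aggregate statistics of the source experiment,
and are *conditions of the simulation*, not empirical claims:

* **Saccadic latency**: shifted lognormal, 157 ms shift, log-scale median
  ~53 ms, σ = 0.68, yielding a grand median near 213 ms with a realistic
  right skew; uniform/random previews are 7 ms slower.
* **Landing position**: 2D isotropic normal per condition with a horizontal
  undershoot bias; neutral-dense previews (uniform/random) land less
  accurately (bias 0.15°, sd 0.5°) than object-like previews (≈0.04–0.05°,
  sd 0.33–0.35°).
* **Manual RT**: lognormal base (median 600 ms, σ = 0.25) plus additive
  condition effects in ms (+12 uniform/random, −16 same, +19 different,
  relative to localized), a linear landing-error slope (40 ms/°), and a
  190 ms penalty on trials whose second refixation was slow. The lognormal
  base makes the pipeline's log transform exactly variance-stabilizing.
* **Additional saccades**: 0/1/2/3 with probabilities 0.007/0.703/0.263/
  0.027; final fixation durations lognormal around 230 ms, so that the
  censoring rules remove roughly 15% of trials.
* **Accuracy**: Bernoulli with logit 3.2 (≈96%) plus +1.4 log-odds for the
  same condition.
* An *intrafixation* mode zeroes the landing structure and condition effects
  and replaces latencies by 175–275 ms exposure durations, emulating the
  fixation-control design.

What the simulator does **not** emulate: sequential dependencies, learning or
fatigue, oculomotor kinematics, subject-specific effect heterogeneity (only
additive subject noise through cell sampling), and any coupling between the
actual stimulus geometry and behavior. Passing tests therefore demonstrate
that the pipeline recovers known structure from data satisfying its
assumptions — not that real data satisfy them.

## Censoring and screening

Two censoring stages mirror the source design exactly, including boundary
semantics: saccade execution (landing Euclidean distance **>** 1.5° from the
display center, or saccade duration **>** 85 ms) and target localization
(**>** 2 additional saccades, or exactly 2 with a final fixation **≥**
240 ms). The stages are order-invariant and idempotent. The 240 ms cutoff
can be re-derived from data (`derive_fixation_cutoff()`): the observed
fixation duration minimizing the absolute difference between the median RT
of fast-refixation trials and the median RT of single-refixation trials,
ties resolving to the smallest value; candidates are the observed durations
(whether the original searched a grid is unknown). Note that this objective
only pins the changepoint when RTs below it actually track the
single-refixation median; on data where all sub-cutoff candidates equalize
medians the argmin is indifferent among them.

Pilot screening of stimulus sets (`screen_stimulus_sets()`) z-scores RTs
within subject, pools them per display, and drops sets with any display mean
outside ±0.6 of the grand mean or accuracy below 75%.

## Statistics

* `survival_hazard()` — discrete-time survival (one minus the cumulative
  proportion) and hazard (events over at-risk) in fixed bins: 5 ms for
  saccadic latencies, 15 ms for manual RTs. The smoothed hazard is a
  centered five-bin moving average; at the edges the window shrinks
  symmetrically (1-, 3-, then 5-bin averages), a choice the source leaves
  open. Survival reconstructs from hazard to 1e-12 by construction.
* `normalize_medians()` — shifts each subject's values so all subject
  medians equal the overall pooled median before pooling; a pure shift,
  leaving within-subject differences untouched.
* `adjust_rt_for_landing()` — regresses log-RT on landing distance (one
  slope, averaged over per-subject fits; the slope is tested against its
  between-subject variability, giving the F(1, S−1) shape) and removes the
  landing term, i.e. regresses each data point to a landing on the display
  center. The adjustment is on the log scale, consistent with the analysis
  being run on log-RTs.
* `condition_contrasts()` — subject × condition cell means analyzed as a
  repeated-measures cell-means model with the subject-by-condition
  interaction as error term: with 5 conditions and S subjects the error has
  4(S−1) df, reproducing the printed F(4, 24) shape at S = 7. The planned
  contrasts ({uniform, random} vs object-like; uniform vs random; same vs
  different; each contour preview vs localized) are reported uncorrected, as
  planned comparisons, with back-transformed ms differences
  (difference of geometric means) and a delta-method ms-scale SE.
* `avov_spread()` — the dispersion comparison: each trial's squared
  Euclidean deviation from its group's mean landing, fed into a one-way
  analysis of variance with an optional two-group contrast. The exact
  formulation in the method's original reference is not reproduced in the
  source; this squared-deviation reading is one standard interpretation and
  is cross-checked in tests against `stats::aov`.
* `accuracy_logistic()` — correctness on condition (uniform reference) with
  subject fixed effects; complete separation raises an error advertising a
  data-augmentation fallback (`penalize = TRUE`, half-weight pseudo-trials
  per cell), which matters at near-ceiling accuracy.
* `landing_isofrequency()` — 2D histogram in 10-px (0.21°) bins; bins are
  accumulated in decreasing count order until they first enclose 90% of the
  landings, plus the marginal median landing point.
* `coarse_shape_analysis()` — minimum-area bounding rectangles (rotating
  calipers over the convex hull) give each contour an aspect ratio and an
  axial orientation; mismatch trials with both shapes elongated (aspect
  > 1.2) enter a per-subject correlation of log-RT with the orientation
  difference (reported in [0°, 90°]), and the cost reduction from excluding
  > 33° differences is reported.

## Worked example

```{r pipeline}
trials <- simulate_experiment(sim_config(), seed = 42)
kept <- censor_trials(trials)
censor_report(kept)

analysis <- kept |>
  filter(correct, rt_ms <= 1500) |>
  adjust_rt_for_landing() |>
  condition_contrasts()
tidy(analysis)
glance(analysis)
```

Reaction times are analyzed for correct, in-time (≤ 1500 ms) responses only;
accuracy analyses keep all completed trials.

```{r survival-plot, fig.height = 5}
trials |>
  normalize_medians(saccade_latency_ms, subject_id) |>
  survival_hazard(saccade_latency_ms, bin_ms = 5, condition = condition) |>
  autoplot()
```

## Numerical choices and problem sizes

Contours are represented analytically and sampled at 4096 points for
polygonal operations (centroids, hulls, inclusion cross-checks); arc-length
tables use 8192-point trapezoidal quadrature, and candidate scoring during
partner selection uses 2048-point grids (the selected pair is re-measured at
full density). Intersections are located by sign changes on the dense grid
refined by bisection to 1e-8 rad. Points radially within 1e-9° of a contour
are treated as ambiguous and rejected rather than classified. Test-suite
simulations use 5–7 subjects with 30–100 trials per condition, 500
null-configuration replicates for type-I calibration and 100 replicates for
CI coverage; stimulus-geometry properties are checked on seeded batches of
12–80 sets. These sizes make every property check cheap to re-run while
keeping Monte-Carlo error well inside the asserted bands.

## Limitations

The compatibility scoring function, the proximity-cue statistic, the
background density floor, the hazard edge handling, and the AVOV formulation
are all places where the source design is underdetermined; each is
implemented as a documented, configurable choice rather than a claim about
the original toolbox. Empirical effect sizes from the source experiment are
used only as simulator defaults and parameter-recovery targets — the package
makes no claim to reproduce them from data.
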