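---
title: "Measuring optogenetic valence from fly walking tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring optogenetic valence from fly walking tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optovalence)
```

## The assay and its model

`optovalence` analyzes the banded-light place-preference assay: groups of
flies walk in narrow 55 × 4 mm stadium arenas while a projector lights two of
four equal quadrants (a light–dark–light–dark banding), and each fly's head
position is tracked at 25 frames/s. When the lit quadrants drive an
optogenetic effector, the spatial distribution of the flies reports the
valence — attraction or avoidance — of activating the labelled neurons.

Three families of per-fly statistics summarize an illumination epoch:

* **Preference index**, `PI = (time in light − time in dark) / total time`,
  integrated over the last 30 s of the epoch. `PI ∈ [−1, +1]`; positive
  means attraction.
* **log₂ speed ratio**, `LSR = log2(mean speed in light / mean speed in
  dark)`. Negative means the fly slows down in the light, a locomotor mode
  that by itself accumulates flies in the light.
* **Choice-zone statistics**: within ±3 mm of each light border, every
  transit in and out of the zone is scored by the side it entered from and
  exited to. `ChI = (exits to light − exits to dark) / transits`; `PEDL`
  and `PELD` are the crossing proportions for entries from the dark and the
  light side. These capture the other locomotor mode: turning away at the
  boundary.

Group-level effects are shared-control mean differences: for each metric,
`Δ = mean(test) − (mean(control₁) + mean(control₂)) / 2`, the reference
being the unweighted mean of the two genetic-control group means. Confidence
intervals come from a bias-corrected and accelerated (BCa) bootstrap with
3,000 resamples, resampling flies within each of the three groups
independently and applying the control convention inside every draw.
Replicates are pooled by fixed-effects inverse-variance meta-analysis
(`w_i = 1/s_i²`), intervention effects are expressed as percent of the mean
control effect at the same light intensity, and screens of driver lines are
summarized by least-squares regressions of each locomotor Δ against
ΔPreference with BCa intervals on R².

## Conventions and censoring rules

* The long axis is `x`, origin at the arena's left end, millimetres.
  Quadrants are 0-based and half-open (`[border, next border)`), so a frame
  exactly on a border belongs to the right-hand quadrant deterministically.
* Occupancy is binary at the nominal border. The physical light gradient at
  a border (mean 0.67 mm, range 0.42–1.04 mm) is represented in the
  simulator's speed rule but never creates a third occupancy state.
* All metrics integrate `dt` between valid frames rather than counting
  frames, so dropped frames and irregular sampling shrink the integrated
  time instead of biasing it. Gaps of invalid frames up to 0.2 s are
  linearly interpolated before smoothing; longer gaps stay invalid and are
  excluded from every time and speed sum.
* Censoring is per metric, never per fly: every fly has a PI (a fly
  confined to one side that still moved more than 2 mm of path over the
  epoch is assigned the extreme ±1.0 with `pi_source = "extreme_assigned"`);
  LSR requires movement in both lit and unlit regions (`single_zone`
  otherwise, `no_movement` if stationary); choice metrics require at least
  one zone transit. Consequently `#PI ≥ #LSR` and `#PI ≥ #choice` on any
  dataset. The 2 mm path threshold operationalizes "moved within the zone";
  the rule itself needs some displacement floor and results are insensitive
  to it over 0.5–5 mm.
* Per-frame speed is the step displacement divided by the step duration,
  attributed to the zone of the step's **start** frame; at 25 fps a step is
  tiny relative to a 13.75 mm quadrant, so transition steps are a negligible
  fraction.
* Transit segmentation discards a transit already in progress at epoch
  start (entry side unknown) and one still open at epoch end; a re-entry at
  the same border within 2 frames of an exit merges into the prior transit,
  suppressing pixel-scale chatter at the zone edge (threshold configurable).

## Smoothing

Tracks are smoothed with a centered triangular window spanning 1 s
(25 frames at the nominal rate), weights renormalized at the track edges and
across invalid frames. The kernel is a convex combination, so smoothing can
never leave the data's min–max envelope and it preserves affine signals
exactly.

Smoothing is a denoising step for real video tracking, and it has a known
side effect on speed-derived quantities: positions within half a window of a
zone switch mix the two zones' speeds, attenuating the measured LSR toward 0
when zone dwell times approach the window width. Real tracks need the
denoising; the simulator's tracks are noise-free by construction, so
simulator-based validation computes speeds on the raw coordinates
(`summarize_group(..., smooth = FALSE)`), where the attenuation would
otherwise dominate the quantity being validated. With smoothing on, a
walker that doubles its speed in the light (true LSR +1) measures near
+0.54; on raw coordinates it measures +0.95.

## The synthetic walker

The simulator is a quasi-1-D agent: dominant motion along `x` with small
bounded lateral jitter, since every published metric depends only on `x`.
Per 40 ms frame it updates a pause/walk two-state Markov chain (pause entry
rate 0.2 /s, exponential dwell with 1 s mean), walks at `base_speed`
(8 mm/s) times a lognormal multiplicative noise (CV 0.3), reverses heading
spontaneously at 0.1 /s, and reflects at the arena ends. Two valence
mechanisms are independent by design, mirroring the two locomotor
hypotheses:

* **Speed modulation** (dopaminergic-style): while in a lit region the
  speed is multiplied by `m = light_speed_multiplier`; `log2(m)` is the
  ground-truth LSR. Within the gradient band the multiplier interpolates
  linearly in `x`.
* **Boundary turning** (output-neuron-style): on each fresh choice-zone
  entry the transit outcome is drawn once — cross with the side-appropriate
  probability (`p_cross_dark_to_light` or `p_cross_light_to_dark`) —
  and steering is committed until the zone is exited. Drawing per transit
  (not per frame) makes PEDL and PELD directly parameterizable.

Defaults not fixed by the assay description were chosen once on realism
grounds: `lateral_jitter_sd = 0.05` mm/frame keeps lateral weaving below a
few percent of path length, matching the visually dominant straight-line
walking in these narrow arenas. One root seed yields per-fly sub-streams
derived from a (group, fly) counter, so enlarging a group never perturbs
the flies already simulated; identical `(params, seed)` give identical
tracks.

What the simulator does *not* emulate: 2-D turning kinematics, inter-fly
interactions, wall-following, tracking noise and identity swaps, and any
coupling between the two valence mechanisms (real lines likely mix them).
Pipeline tests passing on simulated data therefore certify the estimators —
the metric definitions, censoring rules, bootstrap and aggregation — not
the biological realism of any particular walking model.

## Statistical choices

* **Bootstrap unit** is the fly. The three groups are resampled
  independently; bias correction uses the fraction of resampled deltas
  below the point estimate, and acceleration the jackknife skewness of
  leave-one-out deltas over the concatenated groups. A degenerate resample
  distribution (e.g. all values identical) falls back to the percentile
  interval with a warning.
* **Hedges' g** compares the test group with the two controls concatenated,
  with the pooled SD and the small-sample factor `J = 1 − 3/(4 df − 1)`.
* **Mann–Whitney p-values** are reported pro forma only (estimation, not
  testing, drives interpretation). `stats::wilcox.test` supplies the exact
  distribution at small combined n and the tie-corrected normal
  approximation otherwise.
* **Power** is estimated by Monte-Carlo simulation of the design: normal
  groups separated by `g` SD, two-sided Mann–Whitney at α. At the study's
  sizes the pooled comparison (n = 45 test vs 90 controls) has power ≈ 0.89
  at g = 0.6. The single-control-size rank comparison (45 vs 45) sits at
  ≈ 0.78 — slightly below the 0.8 that the t-test reaches (0.80), the cost
  of the rank test's efficiency at normal data. A t-test variant is
  available (`power_simulation(..., test = "t")`).
* **Replicate variance** for meta-analysis weights is the variance of the
  replicate's bootstrap delta distribution — the variance of a difference
  of independent means (test mean and control reference), the quantity the
  weighting formula needs. It is isolated in `replicate_variance()` so an
  alternative operationalization can be swapped in one place.
* **Percent-of-control averages** across interventions and intensities are
  unweighted means of percents; a precision-weighted variant is available
  via the `weights` argument.
* Epoch lit-quadrant sets are configurable per epoch; the default keeps
  quadrants {0, 2} lit throughout a schedule, since nothing in the assay
  description alternates the banding between epochs.

## Validation problem sizes

The test suite validates parameter recovery at 100 simulated flies per
speed-multiplier setting (`m ∈ {0.5, 1, 2}`, tolerance ±0.15 log₂ units) and
per crossing-probability setting (`p ∈ {0.2, 0.5, 0.8}`, binomial 95%
bounds on >1,000 pooled transits); BCa calibration over 500 null three-group
datasets of 45 flies each (false-exclusion rate between 3% and 8%); and a
screen-level dissociation with 6 speed-mode plus 6 choice-mode lines at 45
flies per group, where the speed-mode set regresses ΔPreference on ΔLSR with
higher R² than on ΔChI and the choice-mode set shows the reverse.

## Worked example

```{r example, eval = FALSE}
arena <- arena_spec()
schedule <- illumination_schedule(
  illumination_epoch(0, 30, color = "dark"),
  illumination_epoch(30, 90, intensity = 22, color = "red"))

# a line that halves its walking speed in the light (attraction)
groups <- simulate_experiment(
  test_params = walker_params(light_speed_multiplier = 0.5),
  control_params = walker_params(),
  n_per_group = 45, arena = arena, schedule = schedule, seed = 7)

tabs <- lapply(groups, summarize_group, epoch = 2, smooth = FALSE)
mean_difference(tabs$test$pi, tabs$driver_control$pi,
                tabs$responder_control$pi, resamples = 3000, seed = 7,
                metric = "pi")
```

## Known limitations

* The measured LSR under 1 s smoothing is attenuated when zone dwell times
  approach the window width; compare smoothed and raw estimates when speeds
  are large.
* BCa intervals assume enough distinct resampled values; tiny groups (< 5
  flies) trigger the percentile fallback often and should be interpreted
  with care.
* The fixed-effects meta-analysis deliberately omits heterogeneity
  statistics (I², τ²); it answers "what is the common effect if replicates
  share one", not "do they".
* Conditioning scores are position-based only; odor delivery and shock
  hardware are outside the package's scope.
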