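---
title: "Quantifying fly group behavior: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fly group behavior: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysnb)
```

## The problem

Groups of *Drosophila* placed in a circular agar arena differ heritably in
how tightly they cluster. The standard assay records 16 male flies for 10
minutes in a 5.5 cm dish and summarizes each recording with three group
phenotypes:

* **Social distance (SD)** — for each fly at each frame, the mean Euclidean
  distance to every other fly; averaged over flies to a per-frame group SD,
  and over valid frames to one number per recording. Short SD means strong
  clustering.
* **Walking speed** — the frame-to-frame displacement rate, averaged over
  flies and time.
* **Centroid velocity** — mobility of the group's positional centroid,
  evaluated on the fourth quarter (Q4) of the recording where clustering
  phenotypes are most evident.

Recordings are also summarized per quarter (Q1–Q4, four equal time bins) to
expose within-recording dynamics, and per fly as cumulative travel distance.
Cohorts of many lines are then ranked by their mean phenotypes, extreme
lines selected by average rank over SD and centroid velocity, traits
associated across lines by Spearman rank correlation, and condition effects
(e.g. injury) quantified as per-line SD contrasts.

`flysnb` implements this pipeline end to end, together with an agent-based
generator of synthetic recordings so every stage can be validated against
ground truth without any raw video.

## The synthetic-data generator

No generative model of fly social aggregation is implied by the assay; the
simulator is deliberately the *simplest* model that reproduces the two
qualitative regimes observed in real lines — it is a test harness, not a
biological claim.

Each fly is a persistent random walker. Per step (dt = 1/fps):

1. the heading unit vector is blended with the unit vector toward the
   centroid of the other flies, with weight `attraction * dt`;
2. Gaussian heading noise with SD `heading_noise_sd_rad * sqrt(dt)` is added
   (a rad-per-root-second diffusion, so the path roughness is frame-rate
   independent);
3. the fly advances at `base_speed_mm_s * (1 - speed_decay_per_min)^(t/60)`
   — a per-minute multiplicative slowdown;
4. pairs closer than `repulsion_radius_mm` are pushed apart symmetrically
   (hard-core repulsion, which also sets the packing density of a cluster);
5. a fly crossing the wall has its radial overshoot reflected and its
   heading mirrored about the tangent. Reflection (rather than clamping)
   avoids the boundary accumulation that would mimic clustering.

Defaults (chosen once, as plausible for walking flies on agar, and not
revisited): 16 flies, 600 s at 30 fps (phone-camera rate; the assay itself
does not fix one), 55 mm arena, body length 2.5 mm, base speed 8 mm/s,
heading noise 1.2 rad/√s, repulsion radius 3 mm.

Two documented presets map onto the observed phenotypes:

| preset | attraction | speed decay / min | phenomenology |
|---|---|---|---|
| `short_sd` | 1.5 | 0.35 | SD and speed decline over minutes; group settles into a tight cluster |
| `long_sd` | 0 | 0.05 | sustained exploration, roughly stationary SD, modest slowing |

The `short_sd` attraction is deliberately moderate: stronger values collapse
the group within seconds, which contradicts the gradual Q1-to-Q4 decline the
preset is meant to emulate. With 1.5, a 600 s recording shows Q1 group SD
around 7.5–8 mm falling to ~6 mm in Q4, against ~24 mm throughout for
`long_sd`.

`make_cohort()` turns the presets into a synthetic line screen: each line
receives a small lognormal jitter of attraction (×`exp(0.15·z)`), speed
decay (×`exp(0.10·z)`) and base speed (×`exp(0.08·z)`), emulating
genotype-level variation, and is simulated with independent derived seeds
(default 5 replicates per line, the replication level of the original
screen).

**Injury/rearing plasticity** is modeled as a labeled convenience:
`injury_overrides()` adds 4 to attraction and multiplies base speed by 0.6,
*only* for group-reared ("socialized") flies; developmentally isolated flies
are insensitive. This reproduces the qualitative plasticity pattern
(injury-induced clustering requires early-life social experience) and is
explicitly not a mechanistic model.

What the generator does **not** emulate: body posture and orientation,
occlusions and z-stacking on the wall, heterogeneous lighting, courtship or
aggression interactions, and any within-recording behavioral switching.
Passing tests on synthetic video therefore validate the *computation* —
geometry, identity logic, metric algebra — not detector robustness on real
footage.

## Rendering and tracking

`render_frames()` draws each fly as an anti-aliased dark disk (radius 1.1
mm) on a light agar background (gray 200) inside the arena circle, with a
darker exterior (gray 40) so the arena can be re-fit from the frames, and
optional i.i.d. Gaussian pixel noise (default SD 3 gray levels). Noise is
seeded per frame index, so chunked and whole-sequence rendering agree
bit-for-bit.

The tracker follows the minimal standard design for dark flies on uniform
agar:

* **Arena fit** (`fit_arena()`): Otsu threshold, largest bright component,
  holes filled (flies punch holes in the interior mask), center from the
  component centroid and radius from its area — robust because area is
  insensitive to the anti-aliased rim. A circularity check (area radius vs.
  extent radius within 5%) rejects non-circular frames.
* **Detection** (`detect_flies()`): threshold midway between the interior
  median and minimum (adaptive mode; a 20-gray-level contrast floor returns
  zero detections on empty frames rather than segmenting noise), connected
  components filtered to 0.15–5× the expected body area, intensity-weighted
  subpixel centroids.
* **Linking** (`link_trajectories()`): per frame, optimal bipartite
  assignment (an O(n³) shortest-augmenting-path solver shipped with the
  package) on squared displacement from each track's last known position,
  gated at 5 body lengths per frame. Unmatched tracks coast; gaps up to
  `max_gap = 5` frames are filled by linear interpolation and flagged
  `interpolated`; longer gaps surface as `missing` rather than fabricated
  positions. Surplus detections are dropped as spurious. Ties in assignment
  cost resolve to the lowest-index detection, so linking is deterministic;
  with continuous coordinates, exact ties have measure zero and linking is
  invariant to detection order within a frame.

Identity swaps during prolonged contact remain possible in principle. All
group metrics are label-symmetric, so swaps do not bias them; per-fly travel
distance is the one swap-sensitive output, and is documented as such.

Coordinates follow the image convention throughout (origin top-left, x
rightward, y downward, pixel centers at integer coordinates, 0-based frames
and flies in files); `calibrate()` maps pixels to arena-centered mm without
flipping the y axis.

## Metric definitions and numerical conventions

* SD per fly is **mean distance to all others**, not nearest-neighbor: it is
  the unique definition making the group SD a clean double average over
  flies and pairs. A `nearest` mode is retained for sensitivity analysis.
* The overall SD is the **unweighted** time average of the per-frame group
  mean over valid frames; frames with fewer than two valid flies are
  excluded, never imputed.
* Interpolated samples count as positions everywhere; only `missing` samples
  are excluded.
* Centroid velocity defaults to the **IQR-dispersion estimator** — the mean
  of the interquartile ranges of the centroid's x and y coordinates over Q4
  (mm) — matching the assay's definition via positional-centroid
  interquartile ranges. A **displacement estimator** (mean per-frame
  centroid speed over Q4, mm/s) is also computed, since "velocity" suggests
  a rate; both are reported and the configured default feeds the rankings.
  Note the IQR estimator is translation- and scale-equivariant but not
  rotation-invariant (coordinate-axis IQRs rotate); the displacement
  estimator is fully rigid-motion invariant.
* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7), stated here because conventions differ across
  ecosystems and the test oracles hand-roll the same rule.
* Quarter bins are half-open with boundaries at `floor(k·T/4)`; at 600 s ×
  30 fps each quarter is exactly 4500 frames.
* Speed smoothing is off by default (window 1) and recorded in metadata when
  enabled.

## Cohort analytics

Replicates are averaged per line *before* ranking (the alternative —
ranking replicates then averaging — is not used; averaging first is the
natural reading of a line-level screen). Ranks are ascending (rank 1 =
shortest SD / slowest) with midranks for ties; extreme-line selection sorts
by average rank over {SD, centroid velocity} with deterministic
lexicographic tie-breaks.

`spearman_rho()` is implemented directly as the Pearson correlation of
midrank-transformed inputs — exact under ties — with an optional seeded
permutation p-value (`(1 + #{|rho*| ≥ |rho|}) / (n_perm + 1)`, default
10,000 permutations) instead of asymptotic approximations. Constant input
raises an error rather than returning NaN.

Group-comparison hypothesis testing (ANOVA families, paired t, Wilcoxon) is
deliberately out of scope; the pipeline exports tidy CSV tables for
standard statistics software.

## Problem sizes used in validation

The shipped test-and-validation suite simulates at the assay's native scale
where the check depends on it, and smaller elsewhere: metric-oracle checks
use 50 random 16-fly × 200-frame sets; tracking validation renders a 16-fly,
30 s × 30 fps noise-free recording at 5 px/mm (~275 px arena) in 150-frame
chunks; regime recovery simulates the full 3 + 3 lines × 5 replicates × 600
s screen; plasticity uses 2 lines per rearing condition × 4 replicates ×
600 s. Unit tests use shorter recordings (2–90 s) since the properties they
check are duration-independent.

## Known limitations

* The simulator's dynamics parameters are phenomenological; only the
  experiment constants (group size, duration, arena, replication) are taken
  from the assay design.
* The detector assumes dark flies on a brighter, roughly uniform interior;
  heavy vignetting or reflections would need the fixed-threshold mode or
  preprocessing.
* Merged blobs (flies in contact) are not split; the affected frames simply
  yield fewer detections and the tracks coast, which is the honest behavior
  under the no-fabrication policy.
* Single-fly recordings produce speed and travel metrics only; SD is
  undefined and flagged, not zero.

## A worked example

```{r example, eval = FALSE}
library(flysnb)

# one clustering-regime recording at full assay scale
p <- apply_overrides(sim_params(seed = 42), behavior_regime("short_sd"))
traj <- simulate_group(p)
gm <- group_metrics(traj)
gm

# a small cohort: rank lines, pick extremes, associate traits
co <- make_cohort(n_lines_per_regime = 3, reps = 5, seed = 1)
rt <- rank_lines(co, metric_set = c("sd_overall", "centroid_velocity"))
select_extremes(rt, k = 3)
spearman_rho(co$sd_overall, co$walking_speed, n_perm = 10000, seed = 1)
```
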