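---
title: "Relating horizontal and vertical searching intensity in a diving forager"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(forage3d)
```

# The question and the quantities

A diving central-place forager such as a harbour seal searches in three
dimensions: it can slow down and turn more in the horizontal plane
(area-restricted search), and it can devote more of each dive to the
depth layer of interest. Each habit has its own family of foraging
indices, and the two families are usually analysed separately. This
package implements a joint analysis: derive one vertical index and three
horizontal indices from tag records, classify the behavioural context of
every trajectory segment, and model the vertical index against each
horizontal one with that context as covariates.

## Vertical index: standardized bottom time

Tags store each dive as 11 depth readings equally spaced in time plus
the maximum depth. The bottom phase is the time below 85 % of the
dive's maximum depth, with crossing times interpolated linearly between
readings and multiple bottom excursions summed. Raw bottom time `BT`
confounds effort with geometry — deep dives must spend more time
travelling — so it is standardized by the best the animal could have
done:

$$\mathrm{stBT} = \frac{\mathrm{BT}}{\mathrm{duration} - 2 \times 0.85
\times \mathrm{depth} / v_{max}} \in [0, 1],$$

where $v_{max}$ is the individual's maximum vertical speed, estimated as
the 0.95 quantile (linear-interpolation convention, R type 7) of its
pooled per-dive descent and ascent speeds. Leg speeds are defined
consistently with this geometry: descent speed is the bottom-boundary
depth divided by the time from dive start to first bottom entry, and
symmetrically for ascent. Profiles quantized to 11 points can push
`BT` marginally above `maxBT`; the ratio is clipped to 1. A
time-at-depth index (profile area relative to the maximal area at
$v_{max}$; 1 for a square dive at $v_{max}$) is computed for
cross-checking only — it correlates strongly with `stBT` and plays no
role in the models, mirroring how the analysis treats it.

**Quality control.** Two artefacts of this tag type are handled before
any metric: records with interior readings in the upper quarter of the
dive, or spending more than half the duration there, are flagged as
compressed (a missed surfacing merged several dives into one profile);
and dives of at most 5.6 m are dropped entirely, because below that
depth missed surfacings are frequent but undetectable. The 5.6 m
boundary is implemented inclusively (`max_depth <= 5.6` is shallow) for
determinism.

## Horizontal indices

GPS fixes with reported error above 50 m are dropped; tracks are cut
into bouts at gaps of 24 h at sea or 48 h hauled out, bouts of at most
3 h discarded, and each bout linearly interpolated onto a 20-min grid.
Three indices are computed per node:

* `HS` — displacement to the next node over 1200 s. The source analysis
  predicted positions from a Bayesian switching state-space model; this
  package regularizes by interpolation instead (retained GPS error
  ≤ 50 m is small against 20-min displacements) and accepts externally
  supplied positions and states, so a state-space fit can be dropped in.
* `MT` — a two-state hidden Markov model per animal on log step speed
  (normal emissions) and turning angle (von Mises), fitted by
  Baum-Welch with a deterministic quantile-based initialization and
  decoded by Viterbi. The slower state is labelled intensive
  (`MT = 1`). Haul-out nodes are excluded from fitting. If the two
  fitted states differ by less than 0.15 m/s in mean speed the track is
  treated as single-regime and classified by a plain speed threshold —
  a two-state reading of such a track would be arbitrary.
* `RT` — residence time: from the (backward-extended) entry into a
  400 m circle centred on the node to the exit that is followed by more
  than 1 h outside; shorter excursions are bridged iteratively.
  Crossing times are exact (quadratic circle-segment intersections);
  residence is censored at bout boundaries. Nodes within 400 m of a
  haul-out site are masked — their residence measures the site, not
  searching. The implementation walks outward from each node with
  early stopping; the test suite holds it to exact agreement with an
  independent full-scan oracle on seeded random tracks.

For modelling, `HS` and `RT` become `−HS` and `−1000/RT` (RT in
seconds), so that slower movement and longer residence — both signs of
intensified search — move every index in the positive direction, on
comparable scales.

## Behavioural covariates

**Predatory tactic.** Each dive is placed on the bathymetry by linear
time-interpolation between its bracketing fixes, and its distance to the
bottom is `bottom depth − max depth` (negative values occur: location,
bathymetry and tidal errors combine, and the grid is a mid-tide model).
A normal mixture with 1–5 components is fitted to these distances (EM,
BIC selection via mclust, seeded initialization); the component with
mean closest to zero is the benthic one, and the classification
threshold is its upper 95 % quantile in closed form
(mean + 1.645 × sd). A segment is benthic (`Ptactic = 1`) when more
than half its dives are benthic; an exact tie counts as pelagic.

**Resting while diving.** Drifting resting dives descend slowly and
ascend fast, so their skewness `SK` (ascent/descent speed) is large.
Per animal, the `log(SK)` series is segmented at mean shifts with a PELT
search under a squared-error cost normalized by a robust noise scale
(MAD of first differences) and a `3·log(n)` penalty with minimum
segment length 5 — the penalty and minimum length are exposed in the
configuration because the upstream method leaves them open. Segment
mean `log(SK)` values are then classified within animal by a
two-component mixture (resting = the higher component); if only one
component is supported, or the means differ by less than 0.5, the
animal is all active. `RestingD = 1` when more than half a segment's
diving time is resting.

**Trip direction.** Between consecutive haul-out events, the distance
to the nearest bracketing site is smoothed (centred 6 h running mean of
first differences) and the interval is split where the smoothed
difference changes sign (boundary node joins the following section).
Sections are labelled outward (persistent increase starting within 2 km
of the previous site), inward (persistent decrease ending within 2 km of
the next), within-range, transiting (range of one site to range of a
different site), or other.

## Covariate assembly and exclusions

Dives are assigned to the 20-min segment containing their start time
(the assignment rule is a package choice; the source leaves it open) and
averaged per segment. Segments are excluded when more than half their
time is haul-out, surface or shallow-dive time ("surfacing" here is all
time at sea neither in a qualifying dive nor hauled out); when they lie
within the residence radius of a haul-out site; when their direction is
transiting or within-range; or when a model covariate is missing. Each
excluded segment carries exactly one primary reason, in that order, and
per-rule counts are logged. On synthetic data at the default
configuration the exclusion fraction comes out near the 59 % reported
for the real system — an emergent property, not a calibration target.

## Model fitting with resampling

All fitting happens on repeated random subsamples (without replacement;
the subsample size is capped at 80 % of the table when the table is
small, otherwise repeated subsamples would be identical and bootstrap
errors degenerate). Defaults follow the study scale: structure
selection s = 100 repetitions at n = 7000 and α = 0.01; forward
selection 30 repetitions at α = 0.05 keeping terms selected ≥ 1/3 of the
time; 100 bootstrap refits for standard errors.

1. **Random structure.** The full fixed model is fitted by REML with no
   random effect, a random intercept per animal, and a random intercept
   plus index slope; nested LRTs (naive χ² reference, as standard
   software reports; a halved-mixture boundary option would be stricter)
   pick each repetition's winner and the modal structure wins. A
   singular richer fit estimates the extra variance at the boundary and
   therefore loses its test rather than voiding the repetition.
2. **Fixed effects.** Greedy forward selection under maximum
   likelihood: each admissible candidate is refitted, the AIC-best is
   proposed, and kept only if its LRT is significant. Interactions
   require their main effect; the resting-by-index interaction is never
   tested (resting occurs almost exclusively when the animal is already
   horizontally static, so the interaction is confounded with the main
   effect).
3. **Final fit.** REML on the full table; SEs are the standard
   deviation of estimates over seeded subsample refits; marginal and
   conditional R² use the standard variance decomposition, with the
   random-slope contribution computed from the index's first two moments
   in the data. `Direction` enters with `outward` as reference.
4. **Resolution sensitivity.** The segment table is coarsened by
   factors p ∈ {3, 9, 15} (odd, so the majority movement state is
   unique): dive variables are averaged with dive-count weights, `HS`,
   `RT` and `Direction` are recomputed from the thinned trajectory, and
   selection plus fitting are rerun per resolution.

# The synthetic-data generator

The generator is first-class, tested code; it emulates the statistical
structure the analysis assumes plus the tag's artefacts, on a flat
20 × 20 km plane in metres (the study system is a single fjord, so no
geodesy). Defaults are the study's conditions: 14 animals, ~6 months,
20-min GPS target interval with missed and delayed registrations, 11-
point profiles, haul-out events (mean 6 h, at-sea intervals mean 18 h),
a two-state movement chain whose stationary intensive fraction is 0.77,
per-animal maximum vertical speeds uniform on 1.75–2.16 m/s, and
benthic dives overshooting the mapped bottom by N(2.8, 1.5²) m — so the
distance-to-bottom mixture has its benthic mean near −2.8 m, as in the
real system. A synthetic fjord bathymetry (steep near shore, smooth
banks offshore; ESRI ASCII I/O) provides bottom depths.

Movement is a two-state correlated walk with central-place structure:
each trip leaves a haul-out site for a fresh offshore foraging ground
(directed outbound transit), wanders under the two-state chain, steers
away from the domain boundary (persistent wall reflections would fold
steps and bias speed recovery), and returns to the site ahead of each
scheduled haul-out. Directed transit legs are extensive by
construction, which is why the realized intensive fraction of a
simulated deployment sits below the chain's stationary 0.77.

Dives are generated top-down so the analysis has an exact recoverable
truth: each dive's target `stBT` comes from the ground-truth linear
model (study-scale coefficients in `sim_config()$effect_sizes`) given
its true covariates, and the flat bottom duration is solved from the
`maxBT` geometry to hit that target. Two numerical details matter.
First, a dive travelling at $v_{max}$ has `stBT` = 1 whatever its
bottom time, so targets below the geometric floor
$0.15H/(H - 1.7/v_{max})$ (H = sum of inverse leg speeds) are reached by
slowing both legs — which is also the physiological reading of a
low-efficiency dive. Second, the model residual is attached per dive,
drawn once, so that the two-pass packing of dive start times is
deterministic; segment means then follow the linear model with a
residual scale of roughly `resid_sd/√(dives per segment)`. When the
exact segment-scale residual conditions are needed (coefficient-recovery
checks), `simulate_model_table()` generates the segment table directly
from the mixed model on the latent scale, with no clipping, so fitted
coefficients are unbiased for the generating ones.

Artefacts are injected at configurable rates: concatenated double-dive
profiles (missed surfacing) and dives shallower than 5.6 m. Resting
bouts (Poisson starts, exponential durations) produce slow-descent/
fast-ascent dives, two thirds pelagic, during which horizontal movement
is near-zero — reproducing the confounding between resting and apparent
area-restricted search that makes `RestingD` matter in the models.

**What the generator does not emulate.** No prey fields or energetics;
no tides (the mapped bottom is exact up to the configured benthic
offset); GPS error is isotropic Gaussian rather than fix-geometry
dependent; dive shapes are piecewise-linear; state dynamics are
first-order Markov. Passing tests therefore demonstrate that the
implementation recovers known structure under the stated statistical
assumptions — not that those assumptions hold for any particular real
deployment.

# Numerical choices and degenerate inputs

* Quantiles use R's default type 7 (linear interpolation), documented
  wherever a threshold depends on one.
* The shallow-dive boundary is inclusive; the benthic threshold is
  `<=`; exactly 50 % benthic dives in a segment is pelagic; exactly
  50 % resting time is active.
* Residence-time bridging is strict: an excursion of exactly the
  threshold is bridged, longer ends the residence.
* `flag_compressed` requires at least two profile points below the
  25 % boundary to define an interior; v-shaped dives have no interior
  points and pass.
* Dives whose `maxBT` is non-positive (duration shorter than the
  minimum travel time, possible for artefact records) return `NA` with
  a warning count.
* EM for the HMM runs at most 200 iterations with a relative
  log-likelihood tolerance of 1e-6; the von Mises concentration uses
  the Best-Fisher inverse approximation, clamped to [1e-3, 50].
* All stochastic stages take explicit seeds and derive per-repetition
  streams, so selection traces, bootstrap errors and whole pipeline
  outputs are byte-reproducible; mclust's large-sample initialization
  subset is seeded for the same reason.

# Problem sizes

The shipped `fast` profile (4 animals, 15 days, subsamples of 2000,
10–20 repetitions) exercises every stage at desk scale; the `paper`
profile restores the study-scale settings (14 animals, ~180 days,
n = 7000, s = 100, 30 selection repetitions, 100 bootstrap refits).
The test suite and the acceptance script use the fast scale, with the
coefficient-recovery check at the full 14 × 5000-segment table.

# Known limitations

* The movement-type substitute is a discrete-time HMM on the
  regularized track, not the Bayesian switching state-space model of
  the source analysis; absolute `HS` values on heavily thinned tracks
  differ slightly from state-space predictions.
* The time-at-depth index is a geometric stand-in (the original
  reference formula is not reproduced here) and is used only for a
  sign-level correlation check.
* Changepoint penalty and minimum segment length for resting detection
  are defaults exposed in configuration, not values inherited from the
  source method.
* With few individuals the random-slope variance is weakly identified;
  expect boundary (singular) fits and intercept-only selections on
  small simulations.
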