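# forage3d

Tools for asking how a diving central-place forager — the motivating case
is the harbour seal (*Phoca vitulina*) in a fjord system — allocates its
searching intensity between the horizontal plane and the vertical
dimension, from standard biologging records: GPS fixes, dives stored as
11-point time-depth profiles, haul-out events from a wet/dry sensor, and
a bathymetry grid.

The package covers the full analysis chain, and a synthetic-data
generator with known ground truth so every stage is testable without any
deposited tracking data.

## The indices and the model

**Vertical foraging index.** For dive *i*, bottom time `BT` is the time
spent in the lower 15 % of the dive's maximum depth. It is standardized
across depths as

```
stBT_i  = BT_i / maxBT_i
maxBT_i = duration_i − minimum travel time_i
```

where the minimum travel time is the time needed to reach the
bottom-phase boundary (0.85 × max depth) from the surface and back at
the animal's maximum vertical speed (its 0.95 leg-speed quantile).
`stBT` is bounded in [0, 1]: 1 means the dive used every second it could
have spent at its bottom depth.

**Horizontal foraging indices.** From the regularized 20-min track:
horizontal speed `HS`, a two-state movement type `MT`
(0 = extensive/fast-directional, 1 = intensive/slow-tortuous, decoded by
a hidden Markov model on step speed and turning angle), and residence
time `RT` (the time the trajectory stays within a 400 m circle around
each node before leaving it for longer than 1 h). `HS` and `RT` enter
the models as `−HS` and `−1000/RT` so that an intensification of search
moves every index in the positive direction.

**Behavioural covariates.** Each dive is located on the bathymetry and
classified benthic/pelagic by a normal mixture on its distance to the
sea bottom (the component with mean closest to zero is the benthic one;
dives below its upper 95 % quantile are benthic). Resting-while-diving
is detected from mean shifts in log dive skewness (ascent/descent speed
ratio) via penalized changepoint segmentation. Trip sections are
labelled outward/inward/within-range/transiting/other from the smoothed
distance to the haul-out sites.

**Model.** Per 20-min trajectory segment, dive variables are averaged,
heavily hauled-out/surface segments and segments near haul-out sites are
excluded, and linear mixed-effects models

```
stBT ~ a + β1·hFI + β2·RestingD + β3·Depth + β4·Ptactic + β5·Direction
         + β6·hFI:Depth + β7·hFI:Ptactic + β8·hFI:Direction
         + (1 + hFI | animal) + e
```

are fitted for each horizontal index `hFI`, with random-structure choice
by resampled likelihood-ratio tests, forward fixed-effect selection on
repeated subsamples (terms kept when selected in ≥ 1/3 of repetitions),
and bootstrap standard errors — the resampling doubles as a guard
against serial autocorrelation.

## Worked example

```r
library(forage3d)

# generate a segment table with known coefficients and recover them
tab <- simulate_model_table(n_animals = 14, n_per_animal = 5000, seed = 42)
sel <- forward_select_fixed(tab, "neg_HS", random = "slope",
                            reps = 10, n = 2000, seed = 1)
fit <- fit_final(tab, "neg_HS", sel$terms, "slope",
                 boot_reps = 10, n = 2000, seed = 1)
fit
```

```
<mixed_model_fit> stBT ~ neg_HS + RestingD + Depth + Ptactic + neg_HS:Depth + neg_HS:Ptactic, random = slope, n = 70000
           term estimate     se
    (Intercept)   0.4799 0.0053
         neg_HS  -0.0113 0.0103
       RestingD  -0.2772 0.0095
          Depth   0.0020 0.0003
        Ptactic   0.1393 0.0069
   neg_HS:Depth   0.0010 0.0004
 neg_HS:Ptactic   0.0641 0.0178
Random variances:
    component variance      se boundary
    intercept 0.000206 0.00018    FALSE
 neg_HS slope 0.000984 0.00045    FALSE
     residual 0.024300 0.00054    FALSE
Marginal R2 = 0.415, conditional R2 = 0.428
```

The generating values were intercept 0.480, resting −0.278, benthic
tactic 0.138, depth 0.002 per metre, index-by-tactic 0.063 and residual
variance 0.0243: every estimate lands within two bootstrap standard
errors of its truth. The negative resting coefficient (resting dives
drift, so little of the dive is spent at the bottom) and the positive
index-by-tactic interaction (the horizontal–vertical coupling is
stronger for benthic foraging) are the two behavioural signals the
analysis is built to expose.

The full mechanistic pipeline — tracks, dives, haul-outs, bathymetry,
classification, assembly, models — runs from one call:

```r
res <- run_pipeline(pipeline_config("fast"), out_dir = "run1", seed = 11)
res$mixture
#> <mixture_fit> K = 4, benthic component mean -2.84 m, threshold -0.23 m
res$manifest$counts$pct_excluded
#> [1] 59
```

A thin command-line wrapper lives at `inst/scripts/forage3d.R`.

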