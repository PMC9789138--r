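# detachmon

Quantitative monitoring of enzymatic cell detachment from lens-free
imaging time-lapses.

## The problem

Harvesting adherent cells with proteolytic enzymes (trypsin, TrypLE) is
usually stopped when an operator decides the culture "looks detached" —
a call that is neither standardised nor reproducible, while over-exposure
to the enzyme damages the cells. Lens-free imaging reconstructs, for every
acquisition, a *phase* image (equivalent to phase contrast) and an
*intensity* image (equivalent to bright field). A spread, attached cell is
visible in the phase image only; a detaching cell balls up and produces a
compact **bright region in the intensity image**. `detachmon` turns that
contrast into an endpoint rule for cell-culture engineers and imaging
scientists who need an objective harvesting time.

## The method

Per frame, with both images normalized to [0,1]:

1. **Cell segmentation** — a random forest classifies phase-image pixels as
   cell/background from a 6-family × 6-scale filter bank
   (σ ∈ {0.7, 1, 1.6, 3.5, 5, 10} px; 36 selected features, 48 channels).
   The mask is cleaned by filling holes < 200 px (4-connectivity) and
   removing objects < 50 px (8-connectivity).
2. **Detached-region extraction** — threshold the phase image at 0.65 and
   the intensity image at 0.35; OR the bright masks; fill holes < 1000 px;
   AND with the cell mask; drop seeds < 30 px; dilate the seeds with a
   5-px disk; AND with the cell mask; reassign attached remainders < 50 px
   to the detached mask.
3. **The feature** — the percentage of detached cell regions,

   pct = 100 · |detached| / |cell|,

   tracked over the time-lapse (default: one frame pair every 20 s for
   20 min). Harvesting is stopped at the first frame with pct ≥ 92.5%; if
   the threshold is never reached, the final percentage is reported
   instead. Mean cell circularity (4πA/P², Crofton perimeter) is provided
   as the classical comparison baseline.

A seeded synthetic generator (paired phase/intensity frames with exact
pixel-level ground truth, three density regimes, biphasic detachment
kinetics with a re-attachment phase) makes the whole pipeline testable
without an instrument.

## Worked example

```r
library(detachmon)

# train the pixel classifier on sparse-labelled synthetic frames
ts    <- synthetic_training_set(seed = 11)
model <- train_pixel_classifier(ts$images, ts$labels, seed = 11)
model
#> <pixel_model> 100 trees, 48 channels, seed 11 (OOB error 0.0039)

# simulate a 60-frame harvesting time-lapse and profile it
scene <- simulate_scene(kinetics_params(seed = 23), canvas = c(192L, 192L),
                        regime = "medium", duration_s = 1200)
prof  <- build_profile(scene_time_lapse(scene), model)
head(prof[, c("frame_index", "time_s", "cell_area_px",
              "detached_area_px", "percent_detached")], 4)
#>   frame_index time_s cell_area_px detached_area_px percent_detached
#> 1           0      0         9868                0          0.00000
#> 2           1     20         9157             1786         19.50420
#> 3           2     40         8770             2110         24.05929
#> 4           3     60         8405             2478         29.48245

inhibition_time(prof)                      # default threshold 92.5%
#> threshold not reached (83.0%)
inhibition_time(prof, threshold_pct = 80)
#> inhibition time: 15.7 min (threshold 80%)
```

This simulated donor plateaus at 83% detached area, so the 92.5% endpoint
is not reached within the 20-min window and the final percentage is
reported — the same behaviour seen in slow (overconfluent) cultures. At a
relaxed 80% threshold the first crossing is at 15.7 min (the ground-truth
masks cross at 15.0 min). Validation against exact synthetic truth:

```r
fx  <- generate_validation_set("overconfluent", count = 16, seed = 7)
run_validation(fx, model)
#> <validation_report> overconfluent regime, n = 16: absolute error 1.66% +/- 0.96
```

i.e. the automated percentage tracks the pixel-level ground truth within
~1.7 percentage points on average in the hardest (clumped, overlapping)
regime.

A command-line front end wraps the same functions:

```sh
detachmon simulate --out sim/ --regime high --frames 60 --seed 7
detachmon train    --out model.bin --seed 11
detachmon profile  --model model.bin --manifest sim/manifest.csv --out profile.csv
detachmon inhibition --profile profile.csv --threshold 92.5
```

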