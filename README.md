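# deltasphere

Frame-to-frame **Delta segmentation** and phenotype profiling of live
spheroid time-lapse images.

3D spheroid cultures — here, human induced pluripotent stem cell (hiPSC)
aggregates in 96-well V-bottom plates — are easy to image by phase-contrast
time-lapse but hard to segment: bright halos, dust and well edges defeat
plain intensity thresholding. This package implements a segmentation
strategy that uses time instead of intensity: between two consecutive
hourly frames only the growing spheroid moves, so the pixel-wise absolute
difference of consecutive frames (the *Delta image*)

```
Delta_t = | G_sigma * I_t  -  G_sigma * I_(t-1) |
```

cancels all static structure. Pixels with a difference of 0 are background;
differences at or above the threshold (default 1 native intensity unit)
mark the moving spheroid. Small components are removed, the largest
surviving object is dilated ("pixel expansion") and hole-filled — one mask
per timepoint.

On top of the segmentation the package provides:

* **Morphometry** — per-timepoint shape features on the Delta mask: area,
  perimeter (corner-corrected chain code), form factor `4*pi*A/P^2`,
  moment-ellipse axes, eccentricity, width-to-length ratio, solidity,
  extent, centroid.
* **Profiling** — z-scored features, pooled PCA over all (well, timepoint)
  records, and per-timepoint separation statistics (condition-centroid
  distance and silhouette in PC1-2) that quantify how a self-renewing (E8,
  round) and a differentiating (KSR+BMP4, branched) condition diverge over
  a 96 h course.
* **Classification** — a seeded, from-scratch convolutional network
  (grayscale input, a 1→3-channel adapter convolution, then a compact
  batch-normalized CNN or an 18-layer residual backbone, softmax over the
  two conditions), trained with cross-entropy + ADAM on square crops
  centred on the Delta-mask centroid, with a strict **well-level**
  train/evaluation split and a per-timepoint accuracy curve smoothed over
  a 10 h rolling window.
* **A synthetic phantom generator** — ground-truthed round vs branched
  growing spheroids with static halo/dust artifacts, per-frame noise and
  sub-pixel jitter, reproducing the real study's shape (36 wells × 96
  timepoints) so the entire pipeline is testable without microscopy data.

## Worked example

```r
library(deltasphere)

## a small plate: 4 round (E8) and 4 branched (KSR_BMP4) phantom wells
plate <- generate_plate(phantom_config(),
                        phantom_config(phenotype = "branched"),
                        n_wells_per_condition = 4, base_seed = 1)

## segment every well and measure shape over time
feats <- lapply(names(plate$wells), function(w) {
  r <- measure_series(segment_series(plate$wells[[w]]))
  r$well <- w
  r
})
tab <- assemble_table(do.call(rbind, feats), plate$layout)

## profile: pooled PCA, then per-timepoint separation of the two media
res <- run_pca(standardize_features(tab), k = 2)
res
#> pca_result: 760 records, 2 components; var explained: 61.1%, 33.5%

sep <- separation_over_time(res)
roll <- rolling_mean(sep$centroid_distance, 10)
round(c(early = mean(roll[sep$timepoint <= 24]),
        late  = mean(roll[sep$timepoint >= 72])), 2)
#> early  late
#>  0.24  5.83
```

The numbers are what the code printed for this configuration: the two
conditions are nearly indistinguishable in PC space before the branching
onset (hour 20) and separate by an order of magnitude towards the end of
the course — the quantitative counterpart of "round vs branched spheroids
diverge over time".

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/deltasphere.R simulate --n-wells 4 --out-dir plate/
Rscript inst/cli/deltasphere.R features --input-dir plate/ --layout plate/layout.csv --out-dir out/
Rscript inst/cli/deltasphere.R profile  --features out/features.csv --out-dir out/
```

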