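# microtissue

Simulation and quantification of in vitro micro-tissue remodeling assays.

Tendon-derived cells (for example from remnant hamstring autograft tissue
after ACL reconstruction) seeded in collagen-I gels compact the gel around
constraining micro-posts. Releasing the outermost posts triggers further
remodeling: the tissue compacts over 48 h and sometimes detaches from the
remaining posts. The assay's read-outs — relative silhouette area at 48 h,
intact vs released, and protein band intensities from blots and zymographs —
are candidate patient-specific markers of tissue-remodeling capacity, and are
related to patient age, gender and tendon type by per-read-out regression.

This package implements the full measurement pipeline and a first-class
synthetic-data layer so every stage is testable without any external data:

* **Segmentation** — brightfield silhouette area by grey-value thresholding
  (between-class-variance automatic threshold, largest 8-connected component,
  hole fill, pixel count × pixel area), with an automatic fallback to an
  edge-detection route (Sobel magnitude → binarize → subtract from the
  original → binarize → largest component → fill) for frames whose absolute
  intensities cannot isolate the silhouette.
* **Kinetics** — relative surface area `100·A(48 h)/A(0 h)` and
  intact/released classification with release-time estimation (release = the
  silhouette overlaps fewer than two anchored posts for two consecutive
  frames).
* **Densitometry** — band intensities with two-level (global image + local
  lane) background correction, housekeeping ratios (tenomodulin/tubulin,
  αSMA/tubulin), the MMP2 active fraction `active/(active+latent)`, and the
  Tukey-fence (`Q1 − 1.5·IQR`, `Q3 + 1.5·IQR`) loading-control outlier rule.
* **Statistics** — per read-out: multiple linear regression or logistic GLM
  on age, gender (male = 1) and tendon type (semitendinosus = 1), with
  multiple R² or McFadden pseudo-R², and quantile-comparison normality
  diagnostics; results rendered as a per-read-out coefficient table.
* **Synthetic data** — seeded generators for the patient cohort (36
  patients / ~41 tendons, ages 12–55), read-outs with the study's effect
  structure (area slope 0.96 %/y; a 5-fold pro-collagen plateau drop around
  25 y inducing a −15 ng/ml/y linear age estimate; intact log-odds
  0.19/y age effect calibrated to a 10/41 release rate), compacting
  time-lapse image stacks with ground-truth masks, and gel/blot images with
  programmed band amounts.

## Worked example

```r
library(microtissue)

## render a compacting micro-tissue time-lapse (49 hourly frames) and
## segment the final frame
sc <- tissue_scene_params(seed = 1)
rt <- render_timelapse(sc)
fr <- image_frame(rt$frames[[49]], sc$pixel_size, rt$times[49])
segment_frame(fr)
#> <segmentation strategy A: 11469 px = 1.652 mm^2>
rt$areas_mm2[49]         # ground truth
#> [1] 1.652112

## compaction read-outs for the whole series
ser <- area_series("demo", rt$times, rt$areas_mm2)
classify_release(ser, rt$masks, sc$post_layout)
#> <compaction demo: intact, 41.3% relative area>
```

The segmented area (1.652 mm²) matches the ground-truth mask area to 0.01%,
the tissue stayed anchored, and its silhouette at 48 h is 41.3% of the 0 h
area — i.e. the tissue compacted to roughly two fifths of its starting
footprint.

The full pipeline (cohort → imaging → segmentation → gels → densitometry →
regression table) runs as one deterministic call:

```r
run_demo(list(seed = 42), "demo_run")
```

which writes `cohort.csv`, per-tendon image stacks, `compaction.csv`,
`bands.csv`, `merged.csv` and a per-read-out regression table
(`table2.csv` / `table2.txt`) with estimate, standard error and p-value per
covariate and the fit statistic per read-out. A thin command-line wrapper
lives at `inst/cli/microtissue.R` (`demo`, `segment`, `validate`
subcommands).

## Package layout

| Path | Contents |
| --- | --- |
| `R/cohort.R`, `R/effects.R` | cohort and read-out generators with numerical calibration |
| `R/render_tissue.R`, `R/render_gel.R` | seeded scene renderers with ground truth |
| `R/threshold.R`, `R/components.R`, `R/segment.R` | thresholding, connected components, strategies A/B and fallback |
| `R/kinetics.R` | area series, relative area, release classification |
| `R/densitometry.R` | migration calibration, band quantification, ratios, outlier rule |
| `R/stats.R` | regression layer and results table |
| `R/pipeline.R` | config validation and the deterministic demo run |
| `vignettes/microtissue-methods.Rmd` | models, parameters, design choices, limitations |
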