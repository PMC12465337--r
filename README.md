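# neurocult

Longitudinal morphometric and network analysis of neuronal monolayer
cultures from live-cell fluorescence imaging.

When stem-cell-derived neurons are imaged daily for weeks, two things
happen at once: the culture develops — neurites extend, branch, and
fasciculate into bundles while somata condense into clusters — and the
imaging itself stresses it, through photobleaching and phototoxic damage
that can end in abrupt culture death. `neurocult` quantifies both sides
from single-channel images organised by plate, condition, well and day. It
is written for experimentalists running media/substrate/density
optimisation screens on live-imaging platforms, and for method developers
who need a fully synthetic, ground-truthed testbed for culture-image
analysis.

## The metrics

From paired binary soma/neurite masks (produced by the built-in classical
segmenter or ingested from an external pixel classifier), each image yields
five structural metrics plus mean fluorescence:

* **Neurite length** — pixel count of the one-pixel-wide neurite skeleton.
* **Branch points** — merged skeleton junctions (pixels with ≥ 3 skeleton
  neighbours), normalized to skeleton length.
* **Disaggregation Index** — `DI = s0 · m_n / a_n`, with `s0` the average
  soma area at the first imaging day, `m_n` the soma object count and
  `a_n` the total soma area at day *n*. High DI: small, uniformly spread
  somata. Low DI: organised clustering.
* **Cluster Density Factor** — `CDF = m0 / p_n`, with `m0` the initial
  soma count and `p_n` the summed object perimeter at day *n*. High CDF:
  tight, compact clusters.
* **Neurite coherency** — structure-tensor eigenvalue contrast
  `(λ1 − λ2)/(λ1 + λ2) ∈ [0, 1]`, evaluated in neurite-covered sectors of
  an annulus around each soma object and averaged up to image level; an
  indicator of fasciculation.

Per-well trajectories are normalized to the first imaging day; a culture is
excluded from the first day its mean fluorescence drops more than 10%
between successive scans (the death event). Each trajectory is summarised
by its trapezoidal AUC, modelled as
`AUC ~ media + laminin + density + two-way interactions + plate`
with Benjamini–Hochberg correction, and conditions are ranked into a
network score by summing their CDF and coherency AUC ranks.

## Worked example

A synthetic six-day culture with strong clustering and fasciculation,
analysed end to end:

```r
library(neurocult)
library(dplyr)

spec <- culture_spec(seed = 42, n_days = 6, cluster_attraction = 0.25,
                     fasciculation_strength = 0.6, bleach_rate = 0.05)
tc <- generate_timecourse(spec)

first <- rescale_minmax(tc$images[[1]])
base  <- baseline_from_objects(label_somata(segment_culture(first)))
rows  <- purrr::map_dfr(tc$images, image_metrics, baseline = base,
                        coherency = list(reach = 20, n_sectors = 8,
                                         min_cover = 0.02, sigma = 2))
select(rows, day, neurite_length, branch_points, di, cdf, coherency, n_objects)
#> # A tibble: 6 × 7
#>     day neurite_length branch_points    di    cdf coherency n_objects
#>   <int>          <dbl>         <dbl> <dbl>  <dbl>     <dbl>     <int>
#> 1     1            265        0.0377 1     0.0228     0.569        20
#> 2     2            558        0.0645 0.965 0.0231     0.737        20
#> 3     3            733        0.0437 0.778 0.0231     0.756        17
#> 4     4            911        0.0362 0.547 0.0260     0.785        12
#> 5     5           1050        0.0362 0.489 0.0302     0.830        10
#> 6     6           1168        0.0325 0.504 0.0346     0.843         9
```

The trajectories read exactly as the biology would: neurites elongate day
by day (265 → 1168 px of skeleton), the 20 initial somata merge into 9
objects, so the Disaggregation Index falls from its self-normalized 1.0 to
~0.5 while the Cluster Density Factor rises, and coherency climbs from 0.57
to 0.84 as bundles align. Mean fluorescence never drops more than 10%
between days, so no death event is flagged:

```r
detect_death_event(rows$mean_fluorescence)
#> [1] NA
trajectory_auc(normalize_to_baseline(rows$cdf), rows$day)
#> [1] 5.746488
```

A whole factorial screen (simulate → segment → metrics → trajectories →
AUC → factorial model → network score, with all CSVs, config copy and log)
runs from one configuration object:

```r
cfg <- run_config(out_dir = "run1", seed = 11,
                  synthetic = list(n_wells_per_condition = 2, n_plates = 2,
                                   base = list(n_days = 6)))
bundle <- run_pipeline(cfg)
make_report(bundle)     # trajectory figures with death markers, AUC boxplots
```

Disk-based runs replace `synthetic` with `input_root` (TIFFs + a
`manifest.csv`) and a YAML `platemap`. `tidy()` and `glance()` work on the
factorial fits; `autoplot()` on trajectories and fits.

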