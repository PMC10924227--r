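# filametrics

Headless quantification of fluorescently labeled actin filaments in
micrographs: filament detection, topological error checking, overlap
resolution, and length/count/polymer measurement for single images; and
grid-local, photobleaching-corrected intensity thresholding that tracks
the fraction of filamentous actin incorporated into bundles over a time
series. Written for in vitro reconstitution work (e.g. FITC-phalloidin
labeled filaments bundled by fascin, imaged by TIRF microscopy), where
analyses must be reproducible and scriptable rather than interactive.

## The method in brief

**Lengths.** Each micrograph is noise-filtered and background-subtracted
with user-set Gaussians (square kernels of side 7·σ, which keep >99% of
the Gaussian mass), normalized to [0, 1], thresholded by
max(user floor, Otsu), and skeletonized to one-pixel-wide centerlines.
Skeleton objects with more than two endpoints or any branch point
(neighbor counts 1 and ≥3 under 8-connectivity) are flagged as detection
errors — overlapping filaments. Errors are resolved by recorded
segment-level decisions (keep/discard, with kept segments concatenated
through the shared branch pixels), by automatic removal, or left
uncorrected. Filament length is the object perimeter divided by two,
computed as the geodesic step-sum (1 per orthogonal step, √2 per
diagonal step) and converted to micrometers with the camera's
pixel-size factor. Populations are summarized as a histogram (default
3 µm bins), a count, and total polymer.

**Bundling.** On a pre-bundling first frame, the image is segmented into
a grid (default 3×3, absorbing uneven illumination) and each cell gets a
bundle threshold

    T = mean(I_pixels) + 1.8 · sd(I_pixels)

over the filament pixels of the filtered, nonbinary image; ±1.8 SD
covers ~93% of a normal population, excluding the bright tail that
overlapping filaments produce. Linear and exponential fits to
single-filament intensity levels tracked across sampled frames give a
photobleaching correction that rescales the thresholds over time. Every
filament pixel in every frame is then classified single (≤ threshold) or
bundled (> threshold), and the per-frame summary is the
intensity-weighted fraction

    fraction_bundled = ΣI(bundled) / ΣI(all filament pixels),

plotted against time and rendered as an overlay movie (magenta singles,
yellow bundles) for visual verification.

A synthetic-scene generator with exact ground truth (curvilinear
filaments, crossings, bundle events, uneven illumination,
photobleaching, PSF blur, read noise) backs the test suite and provides
fixtures for method exploration.

## Worked example

```r
library(filametrics)

# a synthetic field of 5 filaments with known lengths
scene <- render_scene(scene_spec(
  image_shape = c(200L, 200L), n_filaments = 5L,
  length_distribution = list(type = "fixed", length_um = 5),
  rng_seed = 3))

proc <- preprocess(scene$stack$frames[[1]])
objs <- label_objects(proc$skeleton)
recs <- resolve_all(objs, policy = "none", pixel_size_um = 0.1)
recs[, c("filament_id", "n_pixels", "length_px", "length_um")]
#>   filament_id n_pixels length_px length_um
#> 1           1       51  53.72792  5.372792
#> 2           2       NA 102.19596 10.219596
#> 3           3       46  55.35534  5.535534
#> 4           4       NA  54.35534  5.435534

summarize_filaments(recs, bin_um = 3)$total_polymer_um
#> [1] 26.56346
```

Five rendered filaments produce four records under `policy = "none"`:
two filaments cross and are measured as one 10.2 µm object (rows with
`n_pixels = NA` are unresolved error objects measured by their full
perimeter/2). Re-running with `policy = "decisions"` and a decisions
file — here generated automatically by collinearity — splits that object
into its two ~5 µm constituents. The remaining lengths recover the 5 µm
ground truth to within ~0.5 µm (digitization plus detection at this
pixel size).

The bundling workflow is one call:

```r
series <- make_bundling_series(standard_bundling_spec(rng_seed = 1))
kin <- run_kinetics(series$stack, movie_path = "overlay.avi")
head(kin$results, 3)
#>   frame_index time_s fraction_bundled n_filament_pixels n_bundled_pixels
#> 1           0      0       0.01132876               287                3
#> 2           1     10       0.01128029               287                3
#> 3           2     20       0.03429357               288                9
```

`kin$results$fraction_bundled` tracks the generator's true curve within
±0.05 at every frame; `kin$thresholds` holds the 3×3 calibration grid
and `kin$bleach` the selected photobleaching model.

A thin command-line wrapper covers the same workflows:

```sh
exec/filametrics lengths  -i micrograph.tif -p 0.107 --policy decisions --decisions d.json -o out/
exec/filametrics bundling -i series.avi -p 0.107 -t 10 --grid 3x3 --k-sd 1.8 -o out/
exec/filametrics simulate -s scene.json -o out/
```

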