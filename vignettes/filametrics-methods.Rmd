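---
title: "Quantifying actin filament lengths and bundling kinetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actin filament lengths and bundling kinetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filametrics)
```

# The measurement problem

In vitro reconstitution experiments visualize fluorescently labeled actin
filaments (typically FITC-phalloidin-stabilized, imaged by TIRF
microscopy) to quantify how populations of filaments assemble and how
crosslinkers such as fascin gather them into bundles. Two quantities
dominate such studies:

* the **number and length distribution** of individual filaments in a
  micrograph, from which filament counts over time and the integrated
  amount of polymer are derived; and
* the **fraction of filamentous actin incorporated into bundles** over a
  time series, the kinetic readout of a bundling reaction.

Both are complicated by the same physical facts: filaments adhere to the
coverslip in random orientations and cross each other; illumination is
uneven across the field; and fluorophores photobleach during the
experiment. `filametrics` is a headless (fully scriptable) toolkit that
addresses each of these explicitly.

# Filament detection

Every image passes through the same chain (`preprocess()`):

1. **Noise filtering and background subtraction.** The image is smoothed
   with a small Gaussian (`sigma_noise_px`, default 1 px) and a
   large-Gaussian smoothed copy (`sigma_background_px`, default 20 px) is
   subtracted — a difference-of-Gaussians whose large kernel estimates the
   slowly varying background. Both kernels are square with side
   `kernel_factor * sigma` (default 7), forced odd so the filter is
   centered; a 7-sigma-wide kernel retains `r round(100 * kernel_coverage(7), 2)`%
   of the full 2D Gaussian mass (`kernel_coverage(7)`), so truncation is
   negligible. Boundaries are handled by reflection, and negative
   differences are clipped to zero because downstream thresholds assume
   nonnegative fluorescence.
2. **Normalization** to `[0, 1]` by `(x - min) / (max - min)`.
3. **Detection.** Pixels above `max(min_threshold, T_otsu)` are detected,
   where `T_otsu` is the global histogram threshold maximizing
   between-class variance (`otsu_threshold()`, 256 bins; ties — which occur
   across empty histogram gaps — resolve to the midpoint of the tie range)
   and `min_threshold` is a user floor. The floor and the automatic
   threshold are combined by `max()` so either can only make detection
   stricter.
4. **Skeletonization** (`skeletonize_mask()`): topology-preserving
   parallel thinning (the two-subiteration Zhang–Suen scheme in the
   Lam–Lee–Suen formulation) reduces each detected object to an
   8-connected, one-pixel-wide centerline. Parallel thinning is known to
   erode line ends by a few pixels, so skeleton endpoints are extended
   back through the detection mask along their local direction; without
   this step lengths are biased short by roughly 0.3 µm per filament at
   the default settings.

8-connectivity is used throughout, because filaments routinely step
diagonally and must remain single objects.

# Topology, errors, and overlap resolution

Each connected skeleton component becomes an object (`label_objects()`).
Pixels with exactly one skeleton neighbor are endpoints; pixels with
three or more are branch points. A clean single filament has two
endpoints and no branch point; anything else (more than two endpoints or
any branch point) is flagged as a detection **error** — in practice,
crossing or touching filaments. Objects smaller than `min_object_px`
(default 3 px) are puncta: they are counted separately and excluded from
length statistics, since sub-resolution objects cannot be measured
meaningfully.

Errors are resolved at the level of **segments**: removing the branch
pixels splits the object into branch-free paths, and branch pixels are
grouped into clusters with a record of which segment ends meet where
(`decompose_branches()`). A resolution is an explicit, replayable record
(`resolution_decision()`, JSON on disk): each segment is either kept —
concatenated with others into one continuous filament, bridged through
the shared branch-point pixels — or discarded as fluorescent noise. This
replaces an interactive click sequence with data: the decisions, not the
clicks, are what matter, and a recorded decision file makes a manual
analysis reproducible. `propose_decisions()` automates the common case by
pairing segment ends whose incoming directions at a cluster are most
nearly opposite (collinear continuation); its output is an ordinary
decision record that can be reviewed and edited. Branch-point pixels are
assigned to *every* filament that traverses them, avoiding a length bias
at crossings.

Three policies (`resolve_all()`) mirror the ways a data set can be
processed: `none` (every object, including errors, becomes one filament),
`remove_errors` (error objects are dropped), and `decisions`. Because
crossings merge two filaments into one long object, mean lengths are
ordered `none > decisions > remove_errors` on crossing-rich data — long
filaments cross more often, so dropping errors biases the population
short, while not correcting at all inflates it.

# Length measurement

Skeletonized filaments are one pixel wide, so the length equals the
closed-boundary perimeter divided by two. For a branch-free path this is
implemented as the geodesic step-sum: orthogonal steps count 1 pixel,
diagonal steps `sqrt(2)` (the two are provably equal for unit-width
paths, and the equality is cross-checked in the test suite against an
independent boundary-tracing walk). For branched objects measured under
the `none` policy, the perimeter/2 is computed as the total wire length —
the minimum spanning tree of the pixel adjacency graph with the same
step weights. Pixel lengths convert to micrometers by the user-supplied
camera/magnification factor. `summarize_filaments()` reports the length
histogram (left-closed bins from 0, default width 3 µm), the filament
count, and total polymer (the summed length, the integral of the
distribution).

# Bundling kinetics

Bundling increases fluorescence along crosslinked stretches roughly in
proportion to the number of filaments per bundle. The kinetics workflow
(`run_kinetics()`) quantifies this as follows.

**Calibration (first frame).** The first frame must precede the onset of
bundling, so all filament pixels are singles. The image is segmented
into an `n_rows x n_cols` grid (default 3x3) and, per cell, the bundle
threshold is

    T = mean(I) + k_sd * sd(I)

over the filament pixels of the noise-filtered, nonbinary image, with
`k_sd = 1.8` by default. Single-filament pixel intensities in a cell are
approximately normal, and ±1.8 SD covers
`r round(100 * normal_coverage(1.8), 1)`% of a normal population
(`normal_coverage(1.8)`), so the threshold excludes only the bright tail
— which, in real images, is dominated by pixels where filaments overlap.
"Filament pixels" here are the **skeleton** (centerline) pixels: the
processing order is threshold, binarize, skeletonize, then segment into
the grid, and centerline intensities are far closer to normal than the
full detection mask, whose point-spread-function skirt would both break
the normality rationale and dilute the intensity-weighted statistic
below. Cells with fewer than 10 filament pixels inherit the whole-image
threshold. The grid exists to absorb uneven illumination; on synthetic
scenes with a 2x left-to-right illumination gradient a 3x3 grid
classifies pixels no worse — and typically better — than a single global
threshold, while ever finer grids would eventually track noise, which is
why 3x3 is the default rather than the finest possible.

**Photobleaching correction.** A subset of frames (default 8, spread
evenly) is analyzed to track how the single-filament intensity level
decays. Both `T(t) = a + b t` and `T(t) = A exp(-k t) + c` are fitted by
least squares and the lower-SSE model wins (`fit_bleach_model()`); the
correction factor `correction(t) = T_fit(t) / T_fit(t0)` scales all cell
thresholds over time. Because later frames contain bundles, the per-frame
level is estimated robustly: frames are processed in time order, and each
frame's single-filament level is the **median** intensity of pixels below
a separator placed at `sqrt(2)` times the previous level (the geometric
midpoint between the single and 2x-bundle levels, extrapolated by the
running decay trend). The median is insensitive to truncating the bright
tail, which makes the estimator stable where a mean + SD would ratchet
downward under its own truncation. Per-frame `k_sd` overrides (a JSON
table) are the batch analogue of interactively retuning individual
frames; they apply to the sampled calibration frames.

**A fixed detection level across the series.** Each frame of a time
series is detected at the *calibration frame's* absolute threshold
rather than its own Otsu threshold. Recomputing the threshold per frame
lets it drift upward as bright bundles form, silently dropping dim
single filaments from the mask and corrupting both the bleach fit and
the denominator of the bundled fraction.

**Classification and the fraction bundled.** Every filament pixel is
compared with its cell's bleach-corrected threshold: at or below means
single, above means bundled. The per-frame summary statistic is
intensity-weighted:

    fraction_bundled = sum(I[bundled pixels]) / sum(I[all filament pixels])

Weighting by intensity (rather than pixel counts) makes the metric
respond to bundle expansion — a 3-filament bundle counts more than a
2-filament bundle — and normalizes out variation in the total amount of
actin between experiments. The overlay movie (`write_overlay_movie()`)
renders singles in magenta and bundles in yellow over the grayscale
frame so the classification can be verified visually; it is written with
a raw (uncompressed) AVI codec so every pixel decodes exactly as
written.

# The synthetic-data generator

`render_scene()` draws ground-truth scenes that emulate the relevant
features of TIRF data: curvilinear filaments (smooth bends of bounded
perpendicular amplitude, emulating the high persistence length of
phalloidin-stabilized actin), rasterized one pixel wide as minimal
8-connected Bresenham chains with intensity deposited per unit filament
length (so brightness does not depend on orientation), scaled by a
multiplicative illumination field, stepwise bundle-event multipliers and
exponential photobleaching, then blurred by a Gaussian PSF and degraded
with additive Gaussian read noise. Ground truth (pixel paths, lengths,
per-frame bundled masks and the noiseless intensity-weighted fraction
bundled) is recorded before blur and noise. A fixed `rng_seed`
reproduces a scene bit-exactly.

Defaults are chosen to represent a typical high-magnification TIRF
setup: 0.1 µm pixels, exponentially distributed lengths (mean 7 µm, the
equilibrium-like distribution of spontaneously assembled filaments), PSF
sigma 1.5 px, and 10 s frame intervals. The generator deliberately omits
Poisson shot noise (additive Gaussian read noise keeps scenes exactly
reproducible at a given seed), TIRF evanescent-field depth effects, and
any polymer mechanics; bundling is modeled as an intensity multiplier on
a filament rather than the physical coalescence of two rendered
filaments, so total scene fluorescence is not conserved across a bundle
event. Passing tests on these scenes therefore validates the
*algorithms* — detection, topology, measurement, thresholding,
bleach-correction — not the photophysics of any particular microscope.

The **standard bundling series** (`standard_bundling_spec()`) used in the
package's own validation is a dilute field (8 filaments, mean 4 µm, in a
320x320 field at 0.1 µm/px) with staged bundle events between 50 s and
200 s (including one bundle-expansion event to 3x), bleach rate
0.001 s^-1, and 30 frames at 10 s intervals. Diluteness matters: pixels
where two single filaments merely *cross* carry twice the fluorescence
and are indistinguishable from bundles by any intensity threshold, so
crossing-rich scenes carry a positive offset (up to roughly +0.05–0.08)
in the measured fraction bundled before any bundling occurs. This is an
intrinsic limitation shared with the original interactive analysis — it
is the same reason the bright tail is excluded from threshold
calibration — and the practical remedy is the one used here and
recommended for real experiments: dilute samples with limited overlap
incidence.

# Numerical choices and edge cases

* Constant images normalize to all zeros and produce an empty detection
  mask (legal, with a warning).
* Otsu ties across empty histogram gaps resolve to the gap midpoint; all
  tied thresholds yield identical masks.
* Rasterization rounds half away from zero; R's default round-half-even
  can turn a unit-step polyline into 2-px jumps.
* Thinning is followed by a cleanup pass so no 2x2 block of skeleton
  pixels survives, and tip reclamation is capped (12 px) so it cannot run
  away along a wide blob.
* Segment concatenation across a multi-pixel branch cluster uses the
  shortest bridging path (breadth-first search within the cluster).
  Orderings of kept segments are searched exhaustively (up to 8 segments
  per keep action).
* Exponential bleach fits use Levenberg–Marquardt with a log-linear
  initial decay estimate and fall back to the linear model if the fit
  fails; a degenerate (constant) threshold series returns a constant
  model with correction ≡ 1. Stacks with fewer than 3 frames skip bleach
  fitting with a warning.
* Cells of the threshold grid tile the image as equal rectangles with the
  last row/column absorbing remainders.

# Validation problem sizes

The package validates itself on synthetic data at these scales, chosen
to exercise each property with comfortable statistics: length recovery
on 200 single-filament scenes (240x240 px, lengths 1–20 µm, PSF 1.5 px,
noise SD 4 on a ~27 AU peak; ≥95% of filaments must be measured within
max(0.3 µm, 10%)); policy ordering on 10 crossing-rich micrographs
(256x256); bleach-rate recovery on 5 noisy 30-frame threshold series
(within 10% of the true rate); the standard bundling series above
(curve recovered within ±0.05 at every frame); and the 2x illumination
gradient scene (20 filaments, 256x256) for the grid-size comparison.

# Known limitations

* Individual filaments are not tracked across frames, and elongation
  rates of filament ends are not measured.
* Crossing filaments are indistinguishable from bundles at pixel level
  (see above); the bundling workflow assumes dilute fields.
* Automatic bleach tracking requires that a representative population of
  single filaments remains detectable in the sampled frames; under
  near-total bundling or very strong bleaching (single intensities
  falling toward the detection level) the per-frame k_sd overrides are
  the supported escape hatch.
* The number of filaments per bundle is not counted; the intensity
  multiplier saturates the usefulness of the metric for large bundles.
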