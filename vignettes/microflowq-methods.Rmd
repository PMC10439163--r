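---
title: "Methods: quantifying cellular function in microfluidic microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cellular function in microfluidic microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microflowq)
```

microflowq is a headless toolkit for time-resolved microscopy of blood
cells and other cell suspensions in microfluidic and static assays. This
vignette explains the models behind each analysis stage, the parameters
that matter, what the synthetic fixtures do and do not emulate, and the
numerical choices that were genuinely open.

## Imaging model and conventions

All inputs become a `frame_stack`: an ordered list of frames (grayscale
matrices or RGB arrays) with the two calibrations every physical readout
needs — `fps` (frames per second) and `um_per_px` (micrometers per pixel).
Pixel intensities are arbitrary units and are never rescaled; thresholds
are therefore expressed on the data's own scale (0–255 for 8-bit input,
0–65535 for 16-bit). Coordinates are 0-based, x = column increasing
rightward, y = row increasing downward; ROIs are half-open
`[x0, x0+width)`.

Background removal for videomicroscopy uses a per-pixel median: over all
frames (`static-median`, deterministic, appropriate for rigid channel
walls) or over a sliding window (`rolling`, tolerates slow drift). The
median of a sequence in which a cell occupies a pixel in only a minority
of frames is the wall intensity, so moving objects survive subtraction
while static structure cancels; output is clipped at zero.

## Single-cell tracking velocimetry

Cells in diluted suspensions appear as compact, roughly Gaussian intensity
spots. Detection follows the classic centroid-tracking chain:

1. **Bandpass**: Gaussian smoothing at the noise scale (sigma = 1 px)
   minus a boxcar average at the expected cell diameter. This flattens
   illumination gradients and residual walls while keeping cell-scale
   structure.
2. **Candidate peaks**: grayscale-dilation local maxima of the bandpassed
   image (strictly positive, so flat background never seeds candidates).
3. **Subpixel refinement**: iterated intensity-weighted centroid within a
   disk of the expected diameter. Final moments are taken over a disk
   centered on the *continuous* centroid with antialiased (fractional)
   edge weights; an integer-centered hard mask biases the second moments
   of off-grid particles enough to corrupt eccentricity.

Each detection carries integrated brightness (mass), radius of gyration,
and moment eccentricity `sqrt(1 - lambda_min/lambda_max)`. The user-facing
filters mirror the assay logic: `min_mass` and `min_intensity` reject
debris, `max_diameter` rejects clusters, and `invert` handles dark
cells on bright brightfield backgrounds.

Linking is frame-to-frame assignment restricted to displacements within
`search_range_px`. Competing candidates are grouped into connected
subnetworks of the bipartite track-detection graph and resolved by
minimizing total squared displacement (branch-and-bound, exhaustive for
subnetworks up to 64 pairings, greedy beyond); an unlinked track or
detection costs `search_range^2`. Tracks missing for up to
`memory_frames` are bridged. Trajectories below `min_frames` or below
`min_distance_px` of total path are discarded — raising either is
provably monotone non-increasing in trajectory count.

Speed uses the frame span as elapsed time, `(last - first)/fps`, so
bridged frames count toward time. Two readouts are exposed because the
field uses both: `free` (path distance over time; default) and
`x_channel_flow` (x-displacement over time, for constriction-channel
deformability assays where velocity at fixed driving pressure is the
stiffness proxy; negative x-velocities are flagged rather than dropped).
Tracking-mode area is `pi * Rg^2`, an approximation labeled as such. Per-
cell fluorescence is the mean over detected frames of summed intensity in
a circular aperture at the centroid.

## Suspension velocity profiles

Dense suspensions cannot be tracked cell by cell; instead textural
features (cell groupings) are seeded with Shi-Tomasi corners (minimum
eigenvalue of the 5-px structure tensor, quality threshold as a fraction
of the maximum response, greedy minimum-separation suppression) and
followed with pyramidal Lucas-Kanade optical flow: 3 pyramid levels of
2x2 block averaging, iterative least-squares alignment of an
`window_size_px` square patch, bilinear sampling, convergence at 0.01 px
or 15 iterations. Features are re-seeded every `reseed_every` frames
(default 10) so fast flow does not deplete the set.

The window doubles as the physical credibility bound: a step longer than
`window_size_px` is flagged invalid from that point. This encodes the
documented failure mode — when true displacement exceeds the window the
tracker locks onto the wrong speckle and reports systematically low
velocities (planted 20 px/frame against a 15 px window recovers a mean
near 6 px/frame with under 1% of steps near truth). Users should size the
window above the largest expected per-frame displacement, or raise the
frame rate.

Per-frame summaries exclude steps below `min_step_px` (detection noise)
and report frames with no valid features as missing, never as zero. The
spatial profile assigns each feature's mean velocity to the bin containing
its seeding row, expressed as *signed* distance from the channel
centerline (midpoint of `channel_span`, or of the ROI when unspecified),
so the full-width profile is reported. The bluntness ratio — mean of the
two outermost non-empty bins over the frame maximum velocity — is the
rheology readout: parabolic (Newtonian-like) profiles give small values,
blunted profiles (e.g. aggregation-prone samples) give larger ones. The
frame maximum is estimated as the 95th percentile of valid step
velocities; a raw maximum is hostage to a single mis-tracked feature.

Profile accuracy is validated against bin-averaged analytic profiles at
a tolerance of 5% of the profile maximum. Near walls the integration
window necessarily straddles regions of strongly different speed, so a
bin-relative tolerance is not meaningful where the analytic mean
approaches zero; the absolute-of-maximum scale is the honest one. The
validation conditions (128-px channel, window 9, 5-µm bins, 4% texture
density, 12 frames) were fixed once from that reasoning.

## Adhesion morphology and functionality

**Brightfield.** Adhered cells are detected as particles (same chain as
tracking). The radius of gyration is converted to the uniform-disk
equivalent radius `R = sqrt(2) * Rg` — exact for a flat-topped spread
cell, which is also how the fixtures render cells — and area is
`pi R^2`. Circularity is moment eccentricity (0 = circle). Cells outside
`[min_area_um2, max_area_um2]` are excluded as noise/aggregates; field
density is retained cells per mm².

**Fluorescence.** The membrane channel is binarized — strictly greater
than the user threshold is signal (the package's resolution of an
above-vs-below ambiguity; documented in the function contract) — and
8-connected regions become cells. 8-connectivity avoids splitting thin
protrusions. Per region: rasterized area, centroid, eccentricity,
equivalent radius, membrane texture (s.d. of membrane intensity over
region pixels — a membrane-heterogeneity readout that is exactly zero for
uniform staining), summed above-threshold secondary stain (e.g.
Annexin V; reported as intensity only, no biological interpretation), and
nuclear lobe count as local maxima of the lobe channel above its
threshold separated by at least `min_peak_sep_px`. Regions are indexed
row-major by centroid so annotated image labels match table rows.

**Protrusions.** Filopodia-like protrusions are sharp points on the
circumference of the convex region. The Harris response
(`det - 0.04 trace^2`, 3-px tensor window, sigma-1 smoothing) is computed
on the binarized region; candidates need `corner_sharpness` of the
maximum response, are snapped to the protrusion end (farthest region
pixel within 4 px — smoothing shifts the response peak inside a narrow
apex), must lie on the convex hull circumference (within 1.5 px), and
merge within `min_separation_px` keeping the strongest. The hull
restriction is what excludes the concave notches between protrusions,
which carry Harris responses of similar magnitude. Distances from the
region centroid to each tip are reported in micrometers (min/mean/max).
Planted star fixtures with 3–8 points are recovered exactly across
rotations.

**Transient adhesion.** Cells rolling on or briefly arresting at a coated
surface are detected and linked as in tracking; detections brighter than
`max_intensity` (integrated) are discarded as debris and trajectories
shorter than `min_frames` as noise. Adhesion time is the inclusive span
`(last - first + 1)/fps`, always an exact multiple of `1/fps`. Net
displacement is also reported so a transit-time reading of the same
trajectories remains recoverable.

## Occlusion and accumulation

Selected color planes are binarized per-plane (`pixel > threshold`). The
device map is inferred, not supplied: a per-pixel count of signal
occurrences across all planes and timepoints, thresholded at
`map_threshold` occurrences (default 1, i.e. the union of all signal ever
seen). The default follows the "any signal marks wetted area" logic; the
threshold is exposed because a count above 1 suppresses isolated
spurious pixels in noisy data.

Microchannels (assumed horizontal; rotate via the ROI/pre-processing step
otherwise) are 8-connected regions of the map. Per column the walls are
the extreme signal rows; single-column gaps are linearly interpolated and
walls smoothed with a 5-wide running median, which flattens ±1 px
raggedness. The channel interior used for all percentages is the area
between the smoothed walls, which makes the spatial identity below exact.

Per timepoint and plane: signal area inside the region, percent occlusion
`100 * signal/region`, per-interval accumulation (difference of signal
areas), and the accumulation rate as the least-squares slope of signal
area (µm²) against time (minutes) — both are reported because the
interval series shows instability that a single slope hides. Spatial
occlusion along one channel is the per-column percentage of the
wall-to-wall span covered by signal, indexed from the channel inlet
(proximal = smallest x); its span-weighted mean equals the whole-channel
percentage identically.

## Machine-learning interpretation

Event tables from any workflow (one file per sample) are pooled into a
point-by-feature matrix. Standardization to zero mean and unit s.d. over
the pooled points is on by default: the features mix µm², µm/s, and
arbitrary intensity units, and unscaled Euclidean k-means is ill-posed
across units. Rows with missing values are dropped with a count.

k-means uses `stats::kmeans` with 10 restarts under a user seed. The
scree stage records within-cluster sum of squares for k = 1..k_max and
suggests the elbow as the argmax of the second difference of inertia —
advisory only; the user's k always wins. Cluster ids are renumbered by
descending size with ties broken by center coordinates, so labels are
stable across runs and invariant to point order. The mean silhouette
`(b - a)/max(a, b)` is computed from the full pairwise distance matrix
(exact, suitable for the tens of thousands of events these assays
produce at desk scale) and is reported as undefined for k = 1. The
per-sample × cluster frequency table is emitted in contingency layout
ready for a downstream Chi-squared test, which is deliberately out of
scope.

One geometry note for validation: "k well-separated spherical clusters"
must separate in *all* retained features. After pooled standardization, a
cluster structure confined to one feature compresses that feature's scale
to the separation itself while pure-noise features keep unit variance, so
silhouettes drop and the elbow moves. The bundled three-cluster check
therefore places centers on an equilateral triangle in feature space.

## Synthetic fixtures: what they emulate, and what they do not

Every workflow is exercised against renders with exhaustive ground truth:
Gaussian-spot cells translating at set speeds (sub-pixel positions, no
grid snapping, so detection accuracy is measurable below 1 px);
adhered-cell scenes with disks/ellipses/star polygons, secondary-stain
disks, and Gaussian nuclear lobes; speckle textures advected by an
arbitrary velocity profile; and device stencils filling according to a
planted occlusion schedule, optionally with a device-delineating stain
plane (the analogue of an endothelial membrane stain) so map inference
can be validated against the full geometry. Noise is additive Gaussian
clipped at zero. All renders are bit-identical under a fixed seed.

What passing these tests shows: the algorithm chain recovers known
motion, morphology, and coverage under controlled contrast and noise.
What it does not show: robustness to uneven illumination, focus drift,
optical point-spread blurring, overlapping or deforming cells, and
photobleaching — none of which the generators model. Parameter choice on
real data remains the user's responsibility; the `parameter_sweep()`
harness exists to demonstrate, per dataset, that conclusions are stable
over a reasonable parameter range.

## Numerical choices and degenerate inputs

- Detection requires an odd `diameter >= 3`; even values error.
- Duplicate candidates converging to one particle are merged within half
  a diameter, keeping the larger mass.
- Empty detection sets link to an empty result, not an error; a frame
  with no valid flow features is reported missing, not zero.
- Degenerate (single-pixel) regions count zero protrusions; uniform
  frames yield zero detections and an empty corner set (with a warning).
- Assignment ties in linking are broken by the global
  squared-displacement minimum; remaining ties are resolved by candidate
  order, which is deterministic for a fixed input.
- All randomness (fixture rendering, k-means restarts) flows through
  explicit seeds; re-running any pipeline with the same config and seed
  is numerically identical.

## Worked example sizes

The bundled validation runs use desk-scale problems chosen to exercise
each estimator meaningfully: 10 cells over 50 frames for detection and
linking; planted speeds of 50/125/250 µm/s at 25 fps; a 128-px channel
with ~500 tracked features for profiles; stars of order 3–8 and lobe
counts 1–5; 8- and 32-channel comb stencils; 200–300 points for
clustering. These sizes are stated here as the package's validation
conditions.

## Known limitations

- No AVI container decoding; videos enter as numbered TIFF/PNG sequences
  or multi-page TIFF. Tables are CSV.
- Tracking is 2-D; out-of-plane motion appears as detection dropout.
- The optical-flow stage reports speed of textural features, not of
  individual cells; in very sparse suspensions the tracking workflow is
  the right tool instead.
- Microchannel wall inference presumes flow along x and roughly straight
  channels; strongly curved vessels are handled only at whole-device
  granularity.
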