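---
title: "Measuring EHT contractility from pillar deflection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring EHT contractility from pillar deflection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehttrack)
```

## The measurement model

An engineered heart tissue (EHT) is anchored between two cylindrical PDMS
pillars. When the tissue beats, both pillars bend inward; for a cantilever
of Young's modulus $E$, radius $R$ and length $L$, loaded at height $a$
along its axis, small-deflection beam theory gives a linear
force–deflection relation

$$F \;=\; \frac{3 \pi E R^4}{2 a^2 (3L - a)}\,\delta \;=\; k\,\delta ,$$

so the whole measurement problem reduces to tracking $\delta(t)$, the
reduction of the inter-pillar-tip distance relative to its relaxed
baseline. Conveniently, $k$ expressed in N/m multiplied by $\delta$ in µm
is a force in µN. The default geometry (`pillar_geometry()`: $E$ = 1.5 MPa,
$R$ = 0.25 mm, $L$ = 3 mm, $a$ = 2 mm) describes a typical soft-PDMS EHT
post with $k \approx 0.99$ N/m, so tens of µm of deflection map to tens of
µN — the range of stem-cell-derived cardiac micro-tissues. These four
numbers are platform constants and must be set per rig; every result in µN
scales linearly in $E$ and with $R^4$, which is why the force oracle in the
test suite checks those power laws exactly.

Because absolute forces are hard to compare across platforms, the package
also reports the **axial stress** $F/A$ in µN/mm², where $A$ is the
tissue's projected surface area measured from the same frames. Unlike the
histology-based physiological cross-sectional area, $A$ is available in
every recording, so compaction and stress can be followed day by day.

## Image analysis

Each frame is split at `floor(width/2)`; one pillar is searched per half
and right-half coordinates are reported in full-frame columns. Two
detector modes cover the two ways pillars are imaged:

* **`black_tip`** — tips painted with carbon black under strong
  illumination appear as solid dark discs and the tissue is nearly
  invisible. The half is Otsu-binarized, the largest dark 8-connected
  component is kept, and its unweighted binary centroid (sub-pixel, pixel
  centers at integer coordinates, 1-based rows/columns) is the tip
  position.
* **`mser`** — unpainted pillars under normal illumination, with the
  tissue visible. Maximally stable extremal regions (dark regions whose
  pixel count is stable while the threshold sweeps ±`mser_delta` grey
  levels) are extracted from the artifact-filled grayscale half; each
  region's moment-equivalent ellipse is computed, regions with
  eccentricity above `eccentricity_max` (default 0.75) or area outside
  [`mser_area_min_frac`, `mser_area_max_frac`] of the half (defaults 0.2%
  and 25%) are discarded, and the centroid of the largest survivor is
  returned.

Running MSER on the grayscale half, rather than on a binarized copy, is a
deliberate choice: on a two-level image MSER degenerates into plain
connected components, and a pillar ring that touches the tissue band could
never be separated from it. The multi-level sweep isolates the darker
pillar tip as its own stable region even where tissue wraps around it,
which is exactly the situation transparent-pillar recordings present. The
implementation (in C++) is the standard union-find sweep over the
component tree with the "larger region continues" merge convention and
8-connectivity, matching the connectivity used everywhere else in the
pipeline.

Before detection, small dark speckles (debris, dead cells) are removed:
dark components smaller than `debris_frac` (1%) of the maximum admissible
pillar area are replaced by the median intensity of their immediate
surroundings. Components at pillar scale are never touched.

Otsu's threshold is computed exhaustively over the 256-level histogram
(dark class = intensity ≤ t, ties toward the lowest t); the test suite
checks it against an independent brute-force search computed from the
class definitions.

**Tissue segmentation** (transparent mode) inverts the Otsu mask so the
dark tissue is foreground, adds the detected pillar-region pixels, closes
interior holes (the bright interior of a pillar ring) by border-flooding
the complement with the complementary 4-connectivity, and keeps the
8-connected component that contains both pillar centroids. Pixel count
times the squared pixel size gives the total area; subtracting the
combined pillar footprint `pillar_area_mm2` (default 0.4 mm², a platform
constant subtracted once, floored at zero) leaves the tissue-only area.
Area is computed per frame and summarized as the per-recording median,
which is robust to the small within-beat fluctuation of the projected
area. In `black_tip` mode the tissue is intentionally washed out by the
illumination, so no area (and no stress) is reported.

Pixel size is calibrated as `camera_pixel_um × binning / magnification`
(defaults 6.5 µm, metadata value, 2.0), i.e. 3.25 µm at binning 1; time is
`frame / frame_rate_fps` with frame 0 at t = 0.

## Waveform analysis

The relaxed baseline of the distance trace is its 98th percentile
(`baseline_percentile`): distance is maximal at relaxation, and a high
percentile is robust to single-frame tracking jitter where the plain
maximum is not. $\delta(t)$ = baseline − distance. Negative values within
`neg_clip_px` (0.5 px, converted through the pixel size) are jitter around
the baseline and are clipped to zero; anything larger aborts the recording
as a baseline failure rather than silently fabricating displacement. When
the unloaded pillar spacing is configured, the resting tension is reported
as unloaded − baseline.

Smoothing is a Savitzky–Golay filter, window 11 frames at 100 fps
(rescaled proportionally for other frame rates and kept odd), polynomial
order 3 — wide enough to suppress tracking jitter, short enough that a
~0.3 s contraction upstroke (≈30 frames) passes essentially unchanged;
polynomials up to the filter order pass through exactly, which the tests
assert at 1e-9.

Peaks are accepted only within 20% of the top of the trace's global range
and troughs within 15% of the bottom (`peak_band_frac`,
`trough_band_frac`) — the acceptance-band reading of "20% from the top /
15% from the baseline" is the only one that yields usable accept/reject
rules, and both fractions are configurable. Alternation is enforced by
keeping the most extreme member of any same-type run. A trace whose whole
range is below `min_amplitude_um` (1 µm, about a third of a pixel) is
treated as non-beating and raises the "no peaks" error: without this floor
a static tissue would be "analyzed" through its sub-pixel tracking jitter.

A cycle is trough → peak → trough. Cycles missing a bounding trough, or
whose bounding trough coincides with the first or last frame, are
incomplete and excluded — recordings rarely start at the start of a beat,
and truncated beats bias every per-beat feature. Within each complete
cycle the 10%/90% crossing times of the contraction amplitude (and the
mirrored decay levels in relaxation) are found with linear interpolation
between frames, so kinetics are not quantized to the frame interval.
Velocities default to the maximum |dδ/dt| within the phase (central
differences on the smoothed trace); amplitude ÷ (10–90% time) is available
via `velocity_mode = "amplitude_over_rise"`. The per-cycle period is the
interval to the next detected peak (truncated neighbors still anchor it),
which stays exact even when a rest phase follows the last beat. Per-file
summaries are means over complete cycles; both the mean and the maximum of
per-beat peak force are emitted.

When multiple noise-induced crossings of a 10%/90% level exist, the first
crossing is used, by definition, without error.

## The synthetic-data generator

`generate_waveform()` produces beats with a raised-cosine rise and fall
(independently adjustable `rise_fraction`); with `rise_fraction = 0.5` a
beat is the classic $(1-\cos 2\pi t/T)/2$ pulse. The closed form makes
every kinetic quantity analytic: the level-$p$ crossing sits at
$(r_f T/\pi)\arccos(1-2p)$ after the beat start, giving a 10→90%
contraction time of ≈0.295 s for $T = 1$ s, and a peak contraction
velocity of $A\pi/(2 r_f T)$. `render_video()` rasterizes two pillar
styles (solid dark disc; dark annulus with lighter interior) with
one-pixel anti-aliased edges so the centroid ground truth is sub-pixel,
moves both pillars symmetrically inward by $\delta/2$ (an asymmetry knob
exists; the distance trace is invariant to it), attaches a rectangular
tissue band whose union area with the pillar discs has a closed form, and
adds seeded Gaussian intensity noise and optional debris speckles.
`write_fixture()` writes the TIFF + metadata-txt pair in exactly the
reader's input dialect plus a ground-truth JSON sidecar.

What the generator does **not** emulate: optics (point-spread function,
defocus, shading), deformable tissue texture, intensity flicker, drift of
the field of view, and pillar styles beyond the two above. Tests passing
on these fixtures therefore demonstrate the correctness of the tracking,
segmentation and waveform mathematics under realistic contrast and noise —
not robustness to every artifact real microscopy can produce.

## Validation problem sizes

The validation suite uses a ten-scene compaction series (420×960 px
frames, ~3 mm field of view, band area shrinking ~3-fold, noise sd 5% of
contrast) for tissue-area accuracy, and five beating videos (210 frames,
160×360 px, amplitudes 5–15 px, both pillar styles) plus those scenes for
centroid accuracy; measured errors are ~0.2% for both, comfortably inside
the ≤5% (area) and ≤1% (distance) bounds the method is expected to meet.
These sizes were chosen so the whole suite runs on a laptop-class single
core; accuracy is scale-free in the pillar radius once it exceeds ~20 px.

## Known limitations

* Exactly two pillars, one per image half; multi-pillar layouts and
  fluorescence tracking are out of scope.
* Per-frame detection failures fail the whole recording (listed in
  `errors.txt`) by design; there is no interpolation across bad frames.
* The beam equation is linear small-deflection theory; very soft or very
  long posts with large deflections would need a nonlinear correction.
* The manual mode is declarative (per-file JSON of extrema indices or an
  analysis window) rather than interactive, so supervised runs are
  scriptable and reproducible.
* Recordings are processed serially; results are defined to be independent
  of processing order, so external parallelization over files is safe.
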