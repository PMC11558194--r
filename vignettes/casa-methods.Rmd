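---
title: "Methods: simulation, tracking and motility analysis for dark-field CASA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, tracking and motility analysis for dark-field CASA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

casakit implements a complete computer-assisted sperm analysis (CASA)
pipeline for dark-field microscopy video — the imaging geometry used by
compact LED-array microscopes, where sperm heads appear as bright blobs on a
dark background — together with a synthetic-data generator that makes every
stage of the pipeline testable against exact ground truth. This vignette
explains the models, the parameters that matter, the numerical choices, and
what the synthetic validation does and does not establish about real data.

```{r setup}
library(casakit)
```

## Motility parameters

For a head trajectory sampled at `M` uniformly spaced times `dt` apart, with
coordinates $(x_j, y_j)$ in µm, the pipeline reports the standard WHO-style
kinematic parameters:

* **VCL** (curvilinear velocity): the summed point-to-point path length over
  the elapsed time,
  $\mathrm{VCL} = \sum_{j=1}^{M-1} \sqrt{(x_{j+1}-x_j)^2 + (y_{j+1}-y_j)^2} \,/\, (M-1)\Delta t$.
* **VSL** (straight-line velocity): the start-to-end displacement over the
  same elapsed time.
* **VAP** (average path velocity): the VCL formula applied to the 5-point
  moving average of the coordinates — the "average path" that strips the
  side-to-side head wobble from the overall direction of travel.
* **LIN** = VSL/VCL, **STR** = VSL/VAP, **WOB** = VAP/VCL: dimensionless
  path-shape ratios, stored as fractions and reported as percentages. By
  construction LIN = STR × WOB whenever all three are defined.

Two numerical conventions deserve attention because downstream numbers
depend on them:

**Clip duration.** A "1 s at 30 fps" clip is represented as 31 samples
spanning 30 inter-frame intervals, so the `(M − 1)Δt` denominator equals the
nominal duration exactly. `video_duration()` follows the same convention.

**Smoothing at the track ends.** A centered 5-point window is undefined for
the first and last two samples. We shrink the window *symmetrically*
(half-width `min(2, k − 1, M − k)`), so the smoothed sequence keeps all `M`
points and — critically — preserves the two endpoints. The alternative,
truncating the window asymmetrically to whatever indices exist, pulls the
smoothed endpoints toward the interior; that shortens a *straight* path
(VAP = v(M−3)/(M−1) instead of v) and lets VSL exceed VAP on wobbly tracks.
With the symmetric rule a straight constant-speed swimmer satisfies
VCL = VSL = VAP exactly and every track satisfies VSL ≤ VAP ≤ VCL, which the
test suite asserts. VAP (and STR, WOB) are reported only for tracks with at
least 7 samples, so the window has interior support; VCL and VSL need only 2.

Ratios are undefined (reported `NA`) when their denominator is zero: a
stationary track has well-defined zero velocities but no meaningful shape.

The production implementation (`compute_motility()`) is vectorised; an
independently coded brute-force reference (`ground_truth_motility()`,
explicit loops, no shared code) exists solely so the two can check each
other. The test suite requires agreement to a relative error below 1e−9 on
1,000 random tracks.

## The synthetic sperm model

`simulate_tracks()` generates ground-truth head trajectories from a minimal
kinematic model chosen to reproduce the qualitative structure of real CASA
records (VCL > VAP > VSL, WOB < 1) with as few parameters as possible:

* a **center path** advancing at a per-cell speed drawn from a normal
  distribution truncated at zero (default 30 ± 5 µm/s), whose heading
  performs a Gaussian random walk (default diffusion 0.3 rad²/s — gently
  curving paths with LIN broadly in the 0.4–0.7 range);
* a **sinusoidal lateral wobble** of the head about the center path
  (default 2 µm amplitude at 5 Hz, uniform random phase per cell), directed
  along the instantaneous path normal;
* an **immotile fraction** (default 0.2) of cells with zero progressive
  speed and no wobble;
* independent per-frame **positional noise** (default 0.05 µm) on every
  head position.

The model is two-dimensional: analysis chambers for CASA are typically
~10 µm deep, which suppresses vertical excursions relative to the lateral
scales measured here. Cells whose head leaves the field of view are
truncated at the exit frame rather than reflected, which both mirrors real
recordings and exercises the pipeline's variable-track-length handling.
Flagellar waveforms, hydrodynamic interactions and cell–cell collisions are
not modelled.

Temperature enters through a linear response model
(`temperature_model()`, `apply_temperature()`): the mean progressive speed
shifts by `speed_slope × (T − T_ref)` (default 1.5 (µm/s)/°C from a 26 °C
reference) while the wobble parameters stay fixed, consistent with
observations that warming speeds sperm up without changing the amplitude of
head wobble. Note that the recovered *VCL*-vs-temperature slope is smaller
than the imposed *speed* slope by the factor `v/√(v² + v_wobble²)`, because
VCL includes the temperature-independent wobble contribution.

## Dark-field rendering

`render_video()` turns ground-truth tracks into 8-bit video. Each head is an
anisotropic Gaussian intensity profile (RMS half-widths 1.8 × 1.1 µm by
default) oriented along its instantaneous heading, on a uniform background
(level 20) with additive Gaussian read noise (SD 8); the peak head signal is
200 gray levels above background. Segmentation and tracking use only the
head centroid, so photometric realism beyond blob shape and SNR is
deliberately out of scope: no flagellum (dark-field signal is dominated by
the head), no out-of-focus point-spread modelling, no shot noise (SNR is
controlled directly through the peak intensity instead).

At a threshold halfway between background and peak, the above-threshold
area of the default head is `2 ln 2 · π · σ_u σ_v ≈ 8.6` µm², comfortably
inside the 3–30 µm² apparent-area band of human sperm heads; the
`optics_config()` constructor rejects head shapes that leave the band.

**Distractors** stand in for debris and out-of-focus particles: isotropic
Gaussian blobs at fixed anchor positions (with small per-frame jitter) whose
*half-peak-contour* areas are drawn from a configurable range. Two caveats
matter when using them to exercise the area filter. First, the operating
segmentation threshold sits below the half-peak contour, so presented areas
are systematically ~2× larger than drawn, and read noise dilates small
components further: choose distractor ranges with a 3–5× margin from the
filter band. Second, at 1 µm/px a pixel is 1 µm², so "area < 3 µm²" cannot
be resolved reliably; the distractor-specificity tests therefore run at
0.5 µm/px. Anchors keep a configurable clearance (default 10 µm) from all
head positions so distractors never merge with heads.

## Detection

Per frame: threshold → 8-connected component labeling → intensity-weighted
centroids → area-band filter.

The default threshold is **background statistics**: `median + 6·MAD` of the
frame. Otsu's method — the textbook parameter-free choice — is available but
is *not* the default, because it fails on realistic dark-field frames: with
well under 1% of pixels in the foreground, the between-class criterion is
maximised by a split *inside* the background noise (measured: threshold 22.4
on a 20 ± 8 background with 220-peak heads, labelling 38% of the frame as
foreground). The median/MAD threshold is robust to the class imbalance,
deterministic, and parameter-light; at 6 robust SDs the expected false-pixel
rate is ~1e−9 per pixel. A fixed threshold remains available for exactly
reproducible runs, and an optional Gaussian pre-blur (off by default) is
exposed for low-SNR material.

Components are 8-connected (diagonal contact joins), computed by a sparse
union-find over above-threshold pixels. Centroids are intensity-weighted and
therefore sub-pixel; on default-SNR fixtures the RMS centroid error is below
0.5 px (tested). The area filter keeps the **closed** interval
[3, 30] µm² — the band endpoints are included.

Coordinate convention, used consistently everywhere: x runs along columns,
y along rows; µm coordinates place the origin at the *center* of pixel
[1, 1], so `x_um = (col − 1) · pixel_size`. Frame indices are 0-based
(`time_s = frame / fps`); track ids are dense from 1 in order of creation.

## Tracking

`link_tracks()` assembles detections into tracks by *globally cost-minimal*
one-to-one assignment between consecutive frames (a Jonker–Volgenant-style
Hungarian solver), under two rules:

* a **gate**: pairs farther apart than `max_link_distance_um` are
  inadmissible. The default gate is `2 × 100 µm/s × Δt` — twice the
  per-frame displacement of a 100 µm/s cell, faster than any human sperm
  head in routine recordings — so true links are essentially never gated
  out while distant spurious links are;
* an **unmatched penalty** equal to the gate, so the solver prefers any
  admissible link to leaving both endpoints unmatched (maximum-cardinality
  matching among cost-minimal ones).

Optimal assignment was chosen over greedy nearest-neighbour because it is
deterministic and strictly better on crossings; the tests verify it against
exhaustive enumeration of all gated partial matchings on scenes with up to
4 objects. To make the output independent of detection order, detections
are canonicalised by position before solving.

`max_frame_gap` defaults to 0 — no gap closing. In 1 s clips a missed
detection costs one short track, whereas bridging a gap would inject
interpolated positions directly into the velocity formulas. When gap
closing is enabled the gate scales with the number of skipped frames.
Tracks shorter than `min_track_length` (default 2) are discarded;
kinematics prediction, merge/split handling and re-identification across
long gaps are out of scope.

## Validation statistics

`coefficient_of_variation()` implements the paired-agreement CV used to
compare two trackers: `100 × SD(a − b) / mean(c(a, b))`, with the sample SD
and the *pooled* mean of both series. (Defining the denominator as one
method's mean instead changes the value by under 2% when the methods agree;
the pooled form is symmetric.) Agreement below 10% is the conventional
acceptance bar, and the cross-run reproducibility test holds the full
pipeline to it: two renders of the same swimmers under different read-noise
seeds give CVs well under 10% for VCL, VSL and VAP.

`compare_methods()` adds an independent-samples t-test (pooled variance by
default, matching standard practice when no Welch correction is named;
Welch via a flag), and `compare_groups()` the classic equal-variance one-way
ANOVA. Shapiro–Wilk normality and Levene homogeneity checks are computed and
attached as *advisory* diagnostics only — no automatic branching on their
outcome. When both groups are constant, the t statistic is 0 with p = 1 for
identical groups and `NA` otherwise (a documented fallback rather than an
error). `temperature_trend()` fits per-chamber means against temperature by
least squares and calls the trend "increasing" only if the slope is positive
with one-sided p < 0.05.

## Illumination geometry

For LED-array microscopes the package also classifies illumination patterns
into bright-field / dark-field / mixed. An LED at lateral offset `r` and
distance `d` below the sample illuminates at `α = atan(r/d)` (point-source
geometry; refraction through the chamber is not modelled), and the
objective accepts rays up to `θ = asin(NA)`. A pattern is bright-field if
every active LED has α < θ, dark-field if every LED has α > θ, and mixed
otherwise; an LED exactly at θ is *not* counted as bright-field, since
marginal rays are not collected reliably.

The default array — five concentric rings of 1, 8, 12, 16 and 24 LEDs at a
4 mm radial pitch — is placed 20 mm from the sample. Ring pitch and distance
are rarely published for such instruments; 20 mm was chosen so that, at
NA = 0.3, the two innermost rings are bright-field and rings 3–5 dark-field
(θ = 17.46°; ring angles 0°, 11.3°, 21.8°, 31.0°, 38.7°), matching the
qualitative behaviour such instruments report (central LED → bright-field,
third ring → dark-field). At a 40 mm distance the same pitch would put the
third ring at 11.3° — inside the acceptance cone — so that geometry cannot
reproduce the described third-ring dark-field behaviour.

## Problem sizes used in the tests

The validation suite runs entirely on synthetic scenes, sized so the full
suite completes in a few minutes on one core: the end-to-end recovery scene
uses 50 cells for 1 s at 100 fps in a 640 × 640 µm field at 1 µm/px (start
positions ≥ 60 µm apart); the frame-rate and reproducibility analyses reuse
that scene; the distractor study uses 10 cells plus 100 distractors at
0.5 µm/px; the temperature sweep uses six chambers of 60 motile cells at
30 fps. Formula-level checks use 1,000 random tracks.

## What passing tests do and do not show

The synthetic generator produces bright, rigid, non-interacting Gaussian
heads with stationary Gaussian noise. Passing the suite therefore
establishes that the *algorithms* are correct — formulas match independent
references, the tracker is exactly optimal, recovery is unbiased at
realistic SNR — but not that the pipeline is robust to everything real
semen videos contain: focus drift, flagellar signal, debris inside the
3–30 µm² band, cell collisions and clumping, illumination gradients, or
motility patterns (hyperactivated, circular) outside the wobbling
progressive model. Results on real material should be spot-checked against
a reference tracker (e.g. TrackMate, via `read_trackmate()` and
`compare_methods()`) before the pipeline is trusted on a new instrument.

Reference tables in the source publications for such instruments also
print per-population VAP values *below* VSL, which is inconsistent with
STR = VSL/VAP ≤ 1 as printed; the columns there appear transposed. This
package follows the definitions, under which VSL ≤ VAP ≤ VCL always holds.
Population summaries average per-track ratios (mean of LIN_i), not ratios
of means.
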