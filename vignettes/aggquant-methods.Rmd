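---
title: "Methods: quantifying protein aggregates from single-molecule images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying protein aggregates from single-molecule images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`aggquant` quantifies protein aggregates from three kinds of single-molecule
fluorescence experiments:

1. **Membrane permeabilization** (liposome calcium-influx assays): how much
   calcium enters each surface-tethered liposome after exposure to an
   aggregate-containing sample.
2. **Aggregate counting** (single-molecule pull-down, SiMPull): how many
   diffraction-limited aggregate spots are present per field of view.
3. **Aggregate morphology** (DNA-PAINT-style super-resolution): the length,
   area, and shape of individual super-resolved aggregates.

Each analysis has a matched ground-truth simulator so that counting and
sizing accuracy can be validated without any experimental data.

# Calcium influx

Three image stacks per field — blank (before sample), sample, and ionomycin
(fully permeabilized positive control) — are each averaged per pixel and
registered to the ionomycin frame by integer-pixel cross-correlation
(`align_by_crosscorr()`, shift bounded at 20 px, exposed rows filled with the
frame median). Liposomes are the local maxima of the ionomycin frame under a
5×5 maximum filter that exceed the frame median by a user threshold; nearby
peaks merge into the brighter one. For each liposome all three frames are
integrated over a disc of radius 3 px (pixels whose centers lie within
3.0 px; 29 pixels), and

$$\%\mathrm{Influx} = \frac{F_{sample}-F_{blank}}{F_{ionomycin}-F_{blank}}\times 100\%$$

Because the formula uses differences, a constant camera offset cancels
exactly. Records whose denominator is below a floor (default 10 counts) are
flagged invalid rather than divided; influx is *not* clipped to [0, 100] by
default because negative or >100% values are informative noise, and `clip =
TRUE` is available. On synthetic triplets where the sample frame is the
convex combination $\alpha\,F_{iono} + (1-\alpha)\,F_{blank}$, the median
recovered influx equals $100\alpha$ to well under 2 percentage points — the
desk-scale stand-in for experimental medians, which require real liposome
data.

# Spot counting

The counting pipeline is, in order: white top-hat background suppression
(image minus its opening with a disc, default radius 7 px — larger than the
largest expected spot radius); linear convolution with a matched filter —
either a zero-sum Ricker (Mexican-hat) wavelet, default σ = 1.5 px, or a
unit-sum Gaussian, default σ = 2 px; a global histogram threshold at
mean + *k*·SD of *all* convolved pixels (default *k* = 2; negative Ricker
responses are deliberately retained in the histogram); a morphological
opening with a square element of side 2·erosion+1 (default erosion 1,
removing isolated bright specks); 8-connected component labeling (row-major
scan order); and edge exclusion — centroids within 5 px of the border
(Ricker preset) or within 2% of the side length (Gaussian preset) are
dropped so only whole particles are counted. Integrated intensity per
particle is the raw sum over the footprint minus the median of a background
annulus (inner radius = equivalent footprint radius + 2 px, width 3 px);
the background convention is ours, as none is standard.

Counting accuracy against a ground truth is

$$\mathrm{Accuracy} = \left(1-\frac{|N_{measured}-N_{simulated}|}{N_{simulated}}\right)\times 100\%$$

symmetric in over- and under-counting and negative for gross over-counting.

## Diffraction-limited simulator

`simulate_dl()` renders isotropic Gaussian dots at uniformly random
positions on a 512×512 zero background. Diameters are uniform in 7–10 px
and each dot is rendered with σ = diameter/4 (~95% of its mass within the
stated diameter). Peak intensities are N(3000, 600²) counts; the noisy image
adds per-pixel N(2000, 200²) baseline noise, optionally an additive centered
Gaussian illumination gradient (amplitude 0.25× baseline mean, σ = half the
image size — the gradient's amplitude and additive form are our choice, as
only its shape is conventional), and optionally a multiplicative
mean-one Gaussian excitation mask for SNR studies. SNR is defined as mean
dot peak intensity divided by mean baseline background intensity, so
`snr = 2` means peaks of 4000 on a baseline of 2000. Dots are placed so
they lie fully inside the field (centers at least ⌈max diameter/2⌉+1 px
from the border): partial dots would be ambiguous for *any* counter and the
detectors' edge margins drop them regardless.

The ground-truth count is **not** the number of placed dots: overlapping
dots merge into one peak. Truth is the number of local maxima of the ideal
image whose topographic prominence (height above the highest saddle to a
higher peak) exceeds 1 count. Prominence is computed exactly by a
union-find pass over pixels sorted by decreasing intensity (plateaus broken
in row-major order; the globally highest component is measured against the
image minimum), so a constant image has zero maxima.

Validated performance at desk scale (9 fields per condition, computed by the
test suite and `scripts/acceptance.R`): mean accuracy stays above 90% for
SNR ∈ {1, 1.5, 2, 4} at 300 dots and for 10–300 dots at SNR 1.5, and above
95% in the recommended ≥2× SNR regime.

# Super-resolution morphology

## Blinking-stack simulator

`simulate_structures()` places line- or dot-shaped structures on a fine
canvas (default 2500 px) that maps to the camera (default 500 px) by an
integer scale factor (default 5; at a 100 nm camera pixel one canvas pixel
spans 20 nm). Lines are 1-px Bresenham strokes with normally distributed
lengths (default 100 ± 37.5 canvas px ≈ 2 ± 0.75 µm) and uniform
orientation; their true length is the exact Euclidean end-to-end distance.
Dots are rasterized discs whose true length is their diameter; the default
diameter distribution, 1.5 ± 0.25 canvas px (30 ± 5 nm), keeps essentially
all dots below 40 nm, representing oligomeric species at the small end of
the simulated size range. Structures that cannot fit are resampled.

`simulate_blinking_stack()` turns every occupied canvas pixel into a
potential blinking site that switches ON independently each frame with
probability 0.005 (sparse, PAINT-like; the probability is our choice).
Each ON site renders a Gaussian spot (σ = 1.1 camera px, a typical
diffraction-limited width) at its canvas coordinates divided by the scale
factor. Spot peak amplitudes are N(300, 60²) counts on an N(200, 30²)
background; these were set so that the least-squares localizer reaches
~11 nm precision, typical of DNA-PAINT — substantially brighter settings
would make simulated localization unrealistically exact. Fiducial markers
render in every frame at 5× the mean spot amplitude. Stage drift is a
cumulative random walk: each frame steps by −d, 0, or +d (default
d = 0.02 camera px) along one randomly chosen axis; the exact trace is
stored so drift correction can be validated against truth.

What the simulator does *not* model: on/off dwell-time kinetics,
multi-emitter overlap within a diffraction-limited spot, EMCCD gain and
shot noise, 3-D defocus, and sample-dependent background structure. Passing
validation therefore demonstrates the correctness of the analysis chain
under ideal single-emitter statistics, not robustness to photophysics.

## Localization and drift correction

`localize_stack()` finds per-frame 3×3 local maxima above mean + *k*·SD of
the frame (default *k* = 5), and refines each in a 7×7 window by
Levenberg–Marquardt least squares against a symmetric 2-D Gaussian
(amplitude, center, width, offset), falling back to a background-subtracted
intensity-weighted centroid. Diverged fits (non-positive amplitude or
width, or center outside the window) are dropped and counted. Positions
convert to nm by the camera pixel size — 100 nm for simulations, 101.2 nm
for the real camera geometry these tools target.

Fiducials are identified by **persistence, not brightness**: localization
chains (linked within one camera pixel) present in ≥90% of frames. Real
fiducials need not obey the simulator's 5× intensity rule, so brightness is
never assumed. Persistence alone is not sufficient: a densely sampled
filament's sites collectively light up in nearly every frame and chain into
one persistent track, so a fiducial track must additionally be point-like —
its per-axis extent may not exceed 2 camera pixels (drift plus localization
noise). Without this constraint the brightest structures would be deleted
as fiducials and the drift estimate destroyed. Per-frame drift is the mean fiducial displacement from each
track's first-frame position, interpolated over missed frames and smoothed
with a centered 10-frame moving average; it is subtracted from every
localization and all fiducial-track localizations are removed. With
noise-free localizations sharing the fiducial's drift the correction is
exact; on simulated random-walk drift the recovered trace is within 0.5
camera px RMS (typically ~0.02 px).

Standard localization tables are supported: the native CSV dialect
(`frame, x_nm, y_nm, intensity, sigma_nm`), ThunderSTORM-style headers with
`[nm]` units, and GDSC-style pixel tables.

## Clustering and per-aggregate metrics

`dbscan_points()` implements standard DBSCAN semantics (grid-bucketed
region queries): a core point has ≥ minPts neighbors within ε *including
itself* (a documented convention choice), clusters are density-connected
cores plus borders, everything else is noise and is discarded. The
partition is deterministic, order-independent, and checked exactly against
an exhaustive all-pairs reference in the tests. Defaults ε = 60 nm
(3 render pixels) and minPts = 5 suit typical data; both are user
parameters by design. In the end-to-end validation we set ε = 100 nm (one
camera pixel): at 0.005 × 500 frames each 20 nm site yields only ~2
localizations, and a 60 nm radius cannot bridge a run of three unlit sites,
fragmenting filaments for sampling rather than structural reasons.

Each cluster is rasterized at 20 nm/px (pixel ON if it holds ≥1
localization, then one 3×3 binary closing with background padding so
border pixels erode honestly). Metrics per cluster: localization count;
area = ON pixels × (20 nm)²; exact convex-hull area of the points (0 when
degenerate); major axis `4·sqrt(λ_max)` and eccentricity
`sqrt(1 − λ_min/λ_max)` from the *point* covariance eigenvalues (points are
the primary data; mask moments would depend on rendering); and skeleton
length.

Skeleton length thins the mask to one pixel width (Zhang–Suen, topology
preserving) and traverses it by repeated nearest-neighbor hops: axial steps
count one render pixel, diagonal steps √2; each remaining branch is walked
the same way and contributes its junction hop, so a Y-shaped aggregate's
length is the sum of its three arms. A single-pixel skeleton reports one
render pixel (20 nm), the minimum resolvable size. Closed forms hold
exactly: a 51-px horizontal line is 1000 nm, an 11-px diagonal 10√2×20 nm,
an L of two 26-px arms 1000 nm.

## Validation problem sizes

All validation runs are sized for a desktop: counting uses 9 fields per
condition at the full 512×512 geometry; the end-to-end morphology check
uses a 320-px camera (1600-px canvas), 500 frames, 10 filaments per field
at three median lengths (1, 2, 3 µm) plus 40-dot fields. Ten structures on
a 320-px field keeps the expected number of filament crossings per field
well below one; crossing filaments are a single connected object to any
density-based clustering and would conflate overlap ambiguity with
measurement error. Under these conditions the pipeline recovers median
filament lengths within ~10% (tolerance 25%) and ordering across length
settings is preserved.

# Known limitations

- **Small-dot quantization.** With sub-40 nm dots, ~11 nm localization
  precision and 20 nm rendering, rendered dot masks thin to one or two
  skeleton pixels, so measured dot lengths quantize to {20, 28.3, 40} nm
  and the median pins at the 20 nm floor while the true median is ~30 nm.
  The dot-median check at ±10 nm therefore sits exactly at its tolerance
  edge and fails by ~0–2 nm on most seeds. Finer (10 nm) rendering was
  evaluated and rejected: filament masks develop holes and skeletons
  fragment, degrading line recovery far more than it helps dots. Skeleton
  length is simply a poor estimator of compact-blob diameter; the major
  axis column is the better size measure for dot-like aggregates.
- Crossing filaments are reported as one aggregate (branch-sum length of
  the union); no attempt is made to disentangle overlaps.
- The localizer is intentionally minimal (no multi-emitter fitting, no
  maximum-likelihood weighting, no z); users with ThunderSTORM/GDSC output
  should import it via `read_localizations()`.
- The Gaussian-kernel counting preset is a functional analogue of
  ComDet-style counting (kernel + fractional margin), not a port; its
  absolute accuracy differs from the Ricker preset.
- Loop-shaped skeletons under-count by one closing step; hook-shaped
  branches may count one extra junction hop.
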