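# aggquant

Quantification of protein aggregates from single-molecule fluorescence
microscopy images.

Soluble protein aggregates — amyloid oligomers and small fibrils — are
central to neurodegenerative disease but are nanoscopic, scarce, and
heterogeneous. Three single-molecule assays make them measurable: liposome
calcium-influx assays report how strongly aggregates permeabilize lipid
membranes; single-molecule pull-down (SiMPull) counts surface-captured
aggregates as diffraction-limited spots; and DNA-PAINT-style
super-resolution resolves the size and shape of individual aggregates at
~20 nm. `aggquant` provides batch-oriented analysis for all three, plus
ground-truth simulators used to validate counting and sizing accuracy
without any experimental data.

## What it computes

**Per-liposome calcium influx.** Blank, sample, and ionomycin stacks are
averaged, aligned by cross-correlation, liposomes located by a maximum
filter, and each liposome's intensities integrated over a radius-3 px disc:

```
%Influx = (F_sample − F_blank) / (F_ionomycin − F_blank) × 100%
```

**Spot counts.** White top-hat background suppression → matched filtering
(zero-sum Ricker wavelet, or a Gaussian-kernel variant) → global
mean + k·SD histogram threshold → morphological opening → 8-connected
labeling → edge exclusion. Accuracy against a simulated ground truth is

```
Accuracy = (1 − |N_measured − N_simulated| / N_simulated) × 100%
```

where the true count comes from prominence-based maxima counting on the
noise-free image, so overlapping dots that merge into one peak count once.

**Aggregate morphology.** A minimal least-squares Gaussian localizer (or
imported ThunderSTORM/GDSC tables) → persistence-based fiducial
identification and drift correction → DBSCAN clustering (radius ε, minimum
neighbors minPts; noise discarded) → per-cluster localization count, area,
convex-hull area, major axis, eccentricity, and skeleton-based length
(morphological thinning, then nearest-neighbor branch traversal: axial
steps 1 px, diagonal √2, summed over all branches).

## Worked example

Counting simulated aggregates at the recommended 2× signal-to-background
ratio:

```r
library(aggquant)

field <- simulate_dl(dl_sim_params(n_dots = 300, snr = 2, seed = 42))
field
#> <dl_simulation> 512 x 512 px, 300 dots (true maxima count: 294)

particles <- detect_spots(field$noisy, detection_params())
glance(particles)
#> # A tibble: 1 × 3
#>   n_particles median_intensity median_area_px
#>         <int>            <dbl>          <int>
#> 1         287           58873.             22

counting_accuracy(attr(particles, "n_particles"), attr(field$truth, "true_count"))
#> [1] 97.61905
```

300 dots were placed; 294 distinct intensity peaks survive overlap (the
ground truth), 287 are detected, giving 97.6% counting accuracy.

Measuring simulated filament lengths end to end:

```r
p <- sr_sim_params(canvas_size = 1600L, camera_size = 320L, scale_factor = 5L,
                   n_frames = 500L, structure_type = "line", n_structures = 10L,
                   length_distribution = c(100, 20), seed = 7)
truth <- simulate_structures(p)
stack <- simulate_blinking_stack(truth, p)
stack
#> <sr_stack> 320 x 320 px x 500 frames, 10 structures, 2 fiducials

locs <- localize_stack(stack, threshold_k = 5, pixel_nm = 100)
locs_dc <- correct_drift(locs, n_frames = p$n_frames)
clusters <- cluster_localizations(locs_dc, eps = 100, min_pts = 5,
                                  render_pixel_nm = 20)
glance(clusters)
#> # A tibble: 1 × 4
#>   n_clusters n_noise median_length_nm median_eccentricity
#>        <int>   <int>            <dbl>               <dbl>
#> 1         10       0            1875.               1.000

median(truth$structures$true_length_nm)
#> [1] 2164.933
```

Ten simulated filaments are recovered as ten clusters; the measured median
length (1875 nm) is within 14% of the true median (2165 nm), with the
near-1 eccentricities expected of straight filaments.

`autoplot()` methods exist for particle sets, influx tables, and cluster
tables; `run_batch()` drives whole directories of fields of view, and
`inst/scripts/aggquant.R` exposes the same operations as shell subcommands
(`simulate-dl`, `simulate-sr`, `count`, `influx`, `localize`,
`driftcorrect`, `cluster`, `validate`).

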