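---
title: "chipmorph: measurement models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chipmorph: measurement models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipmorph)
```

`chipmorph` quantifies endothelial lumen remodeling in organ-on-chip
devices from three kinds of evidence: top-down fluorescence images of
the channel, segmented label masks of the endothelial monolayer, and
the longitudinal per-chip width tables the first stage produces.  This
vignette is the package's own account of how each stage works, which
knobs matter, and where genuine design freedom was resolved by a
documented choice.

## 1. Projected lumen width

### Measurement model

A chip image is a calibrated raster pair (brightfield + fluorescence)
with the channel running along image rows.  The lumen appears as a
bright band between the two channel walls.  The width stage:

1. computes **one Otsu threshold per image** from the fluorescence
   histogram (256 bins over the intensity range) and multiplies it by
   an **empirical correction factor** (default 1);
2. lays an evenly spaced grid of cross-channel profiles along the
   channel axis: positions `margin, margin + spacing, …, extent −
   margin` with `extent = (n_rows − 1)·pixel_size`, each profile being
   the pixel row nearest its position;
3. on each profile takes the **outermost supra-threshold runs** of at
   least `min_run_px` pixels: the left edge is the start of the first
   such run, the right edge the end of the last.  Profiles with no
   qualifying run are flagged invalid, counted, and excluded from the
   mean — never silently dropped;
4. converts each edge pair to a width `(right − left)·pixel_size` (the
   profiles are perpendicular to the channel axis, so the Euclidean
   distance between the edge points reduces to this 1-D separation)
   and reports the arithmetic mean over valid profiles as the chip's
   projected width.  Several images of one chip are averaged with
   equal weights.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `spacing` | 25 | µm | profile grid pitch along the channel |
| `margin` | 100 | µm | excluded extent at each channel end, where edges may leave the field of view |
| `correction_factor` | 1 | — | multiplier on the Otsu threshold; acquisition-specific |
| `min_run_px` | 3 | px | shortest run accepted as lumen; rejects hot pixels |
| `n_bins` | 256 | — | histogram resolution for the threshold |

The threshold is computed once per image rather than per profile:
single-row histograms are far too sparse for a stable between-class
variance maximum.  Edge localization is at pixel resolution by design —
the method's practical accuracy is set by pixel size, and subpixel
interpolation would suggest a precision the rest of the chain does not
support.  Wall calibration follows the original manual protocol (the
user supplies the left wall column); `detect_wall()` proposes the
leftmost strong dark-to-light transition of the column-mean
brightfield profile as an automated convenience, and a manual
calibration always wins.

Widths are reported per edge-pair *span*: a band occupying pixel
columns `l..r` inclusive has width `(r − l)·pixel_size`, and the scene
generator places its band so that a wall-attached lumen spans exactly
the wall separation.  With the default geometry (400 px separation at
3.25 µm/px) a wall-attached chip therefore measures exactly 1300 µm,
which is the package's reference worked result
(`scripts/acceptance.R`).

### Otsu threshold

`otsu_threshold()` maximizes the between-class variance over all
histogram cuts, using bin midpoints as class values, and returns the
bin boundary of the best cut; ties break toward the lower cut.  A
constant image (single occupied bin) is a degeneracy error, not a
threshold of convenience.  The test suite holds the implementation to
an exhaustive-search oracle over random 8-bit histograms.

## 2. Morphometry

Masks are integer rasters (0 = background) at a known pixel size.  The
stage removes every label touching the outermost rows/columns
(clipped cells bias all descriptors; the operation is idempotent),
then computes per label:

* **area** — pixel count × pixel area; regions *strictly smaller* than
  `min_area` (default 200 µm²) are then filtered out, since such
  fragments are typically inter-cell gaps or segmentation artifacts.
  A region of exactly 200 µm² is retained.
* **aspect ratio** — major/minor axis ratio of the ellipse matching
  the region's second central moments.  Pixels are treated as unit
  squares (adding 1/12 per axis), which makes a single pixel exactly
  round (ratio 1) and an axis-aligned w × h rectangle exactly w/h.
  The moment-ellipse convention was chosen over the bounding-box ratio
  because it is rotation-invariant.
* **Feret diameter/angle** — the maximum caliper distance over the
  label's boundary-pixel corner points (convex hull first, then the
  exact pairwise maximum over hull vertices) and the orientation of
  the maximizing chord, measured counter-clockwise from the image
  horizontal into [0°, 180°).  A brute-force pairwise-distance oracle
  pins this down exactly in the tests.  Note that for compact shapes
  the max-Feret chord of a rectangle is its *diagonal*: angle-recovery
  checks therefore use elongated shapes, where chord and long axis
  coincide to within rasterization error (≈ 2°).
* single-pixel labels: area one pixel, ratio 1, Feret = pixel diagonal.

Group summaries report n, median and quartiles per descriptor using
linear-interpolation quantiles (R type 7); empty groups report n = 0
and no statistics.

## 3. Longitudinal statistics

### The mixed model

Per-chip widths over days follow a multivariate-normal
repeated-measures model: saturated day × group cell means (equivalent
to day + group + day:group with categorical days), **no random
effects**, and one **unstructured covariance** matrix across days
shared by every chip.  Chips that drop out contribute their observed
leading block through the direct likelihood, which is valid under
ignorable (MAR) missingness.

Estimation maximizes the **restricted likelihood**.  The fit groups
chips by missingness pattern and accumulates per-pattern sufficient
statistics (count, sum vector, cross-product matrix), so one likelihood
evaluation costs a handful of ≤ 8×8 Cholesky factorizations regardless
of cohort size; the covariance is parameterized by its Cholesky factor
with log diagonal (every iterate stays positive definite) and maximized
by BFGS with the analytic gradient (the profiled GLS means drop out by
the envelope theorem).  The test suite cross-checks estimates, standard
errors and the estimated covariance against an independent
generalized-least-squares implementation (`nlme::gls` with
`corSymm` + `varIdent`).  Non-convergence and singular covariance
estimates are reported as errors; the package never regularizes
silently.

Predictions are per-cell means with **Wald (normal-quantile) 95 %
intervals**.  REML with Wald intervals is the common default of the
commercial mixed-model software this analysis style originates from;
the choice is recorded in the fit metadata.  On balanced complete data
the cell estimates reduce exactly to per-cell sample means.

### Divergence day

`ci_divergence_day()` compares the two groups' intervals day by day as
*closed* intervals — exactly touching endpoints still count as
overlapping, the conservative reading — and reports the earliest
non-overlap day, or none.  Simulations in the test suite hold this
rule to three properties under the reference design: nominal CI
coverage within [0.90, 0.99] over 200 replicates, recovery of a known
separation day in ≥ 90 % of replicates when the trajectories split by
far more than the noise, and no divergence in ≥ 90 % of null
replicates.

### Kruskal–Wallis and Dunn

`kruskal_dunn()` computes the tie-corrected H referred to a χ²(k−1),
and Dunn's pairwise z statistics with the same tie correction,
two-sided normal p-values and Bonferroni adjustment by default
(unadjusted values are always reported alongside).  Stars follow the
0.05/0.01/0.001 convention.  H is computed in-package from rank sums
so that `stats::kruskal.test` can serve as an independent check in the
tests; all observations identical is a degeneracy error (the tie
correction denominator vanishes).

## 4. Synthetic data: what it emulates, what it does not

The generators define the package's reference study conditions.

**Scenes** (`generate_lumen_scene`): a bright band of prescribed
per-row width between two wall columns, then Gaussian blur, a linear
illumination gradient across the width, and seeded additive Gaussian
noise; the brightfield channel carries dark wall bands.  Defaults:
1200 × 600 px at 3.25 µm/px — covering a 1300 µm channel (400 px wall
separation) with margin, and a along-channel extent of ≈ 3.9 mm,
about two thirds of a 6 mm channel.  The acquisition metadata of real
low-magnification imaging is not public, so these are declared
defaults, recorded in every config, never hard-coded in algorithms.
Additive Gaussian noise is the simplest model sufficient for recovery
testing; camera-specific noise (Poisson, fixed-pattern) is deliberately
out of scope, as are confocal z-stacks and photorealism.  Ground truth
(exact per-row edges) is recorded before any degradation.

**Masks** (`generate_cell_mask`): ellipses (or rectangles) with drawn
area, elongation and orientation, placed by rejection sampling so that
any two labels are separated by at least `min_gap_px` background pixels
(Chebyshev); impossible packings return a partial mask with an explicit
warning.  Real monolayers tile space with touching cells — the gap
exists so that label identity, border contact and Feret geometry are
unambiguous in tests; morphometric conclusions about *packing* cannot
be drawn from these masks.

**Cohorts** (`generate_cohort`): per-chip series from a multivariate
normal with group mean trajectories and a shared unstructured
covariance, thinned by a monotone dropout schedule (chips leave and
never return).  The packaged reference design
(`soc_cohort_design()`) uses days 2, 3, 5–10; a flat control arm
anchored at 1295.42 µm (day 2) and 1304.92 µm (day 10); a remodeling
arm anchored at 1296.04, 1284.32 and 1023.11 µm on days 2, 5 and 10
with smooth interpolation between (day 6 at 1262 µm, the midpoint of
the reported day-6 interval); per-day standard deviations rising from
9.8 to 99.8 µm; correlation 0.7^|lag| between days as a plausible
longitudinal decay (the true inter-day correlation of such cohorts is
unreported); and retained counts control 13, 13, 6, 6, 6, 6, 6, 6 /
co-culture 68, 68, 65, 62, 34, 34, 33, 26.  The observed control count
of 12 on day 2 (vs 13 on day 3) is not representable under monotone
dropout, so the design carries 13 from day 2 — one chip-day more than
observed.  Because the generator is multivariate normal with a common
covariance, passing tests demonstrate correct *inference under the
model's own assumptions*; they cannot detect misspecification
(non-normal widths, group-specific covariance, informative dropout)
in real data.

Determinism: every generator takes an integer seed and produces
bit-identical output for identical config + seed.

## 5. Numerical conventions and degenerate inputs

* Matrices are indexed `[row, column]`, 1-based, channel along rows;
  pixel size is isotropic (µm/px).
* Widths: `(right_px − left_px)·pixel_size` with both edge columns
  inside the band.
* Otsu ties break toward the lower cut; Feret ties keep the first
  maximal chord found on the hull.
* Quantiles: linear interpolation (R type 7).
* Standard deviations use the n−1 denominator; a single-observation
  cell reports an undefined (NA) sd, never 0.
* Degeneracies are errors, not defaults: constant image (Otsu), empty
  profile grid, no valid profile on an image, non-positive-definite
  design covariance, all-identical Kruskal–Wallis input, singular
  covariance at the REML optimum.
* TIFF float storage is defined on [0, 1]; out-of-range intensities
  are affinely rescaled on write with the transform recorded in the
  YAML sidecar, so reads reconstruct original values to 32-bit float
  precision.  Pixel size always travels in the sidecar (or an explicit
  override); a missing pixel size is an error.

## 6. Problem sizes used by the test suite

The packaged checks run at desk scale by choice: the default scene
(1200 × 600 px) yields 148 profiles per image; width-recovery sweeps
use 5 noise-free widths plus 20 noisy seeds; the morphometry oracles
cover ≥ 30 random shapes; the mixed-model study uses 200 simulated
cohorts for coverage and 40 each for divergence recovery and the null,
at the full reference design size (81 chips, 452 observations).  These
sizes give stable Monte-Carlo estimates for the stated tolerances
while keeping a complete run in a few minutes.

## 7. Known limitations

* The channel must run along image rows; rotate images otherwise.
* Edge detection is profile-based by design — the lumen is never
  segmented as a 2-D region, and 3-D reconstruction is out of scope.
* The value of the empirical threshold correction factor is
  acquisition-specific and must be supplied by the user; the default 1
  is plain Otsu.
* The divergence-day rule inherits the conservatism of CI-overlap
  comparisons; it is a reporting convention, not a formal test with a
  controlled error rate.
* Wald intervals ignore small-sample t corrections; with very few
  chips per cell (n ≈ 6) the intervals are slightly anti-conservative,
  visible as coverage a little below nominal in the simulation suite.
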