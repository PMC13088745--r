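# chipmorph

Quantitative image analysis and longitudinal statistics for
organ-on-chip vascular models.

In synovium-on-chip (and similar microphysiological) devices, an
endothelial monolayer lines a microfluidic channel and forms a
perfusable lumen.  As the surrounding tissue remodels, the lumen
detaches from the channel walls and narrows; in top-down fluorescence
images this shows up as a shrinking bright band.  `chipmorph`
implements the analysis chain that turns such images into numbers and
inferences:

1. **Projected lumen width** — cross-channel intensity profiles every
   25 µm (end margins excluded), lumen edges per profile as the
   outermost runs above an Otsu threshold × an empirical correction
   factor, per-profile width `(right − left) · pixel size`, and the
   per-chip mean over valid profiles.
2. **Endothelial morphometry** — from integer label masks (e.g.
   segmented VE-cadherin stainings): border-object removal, a strict
   `< 200 µm²` region filter, and per-cell area, moment-matched-ellipse
   aspect ratio, maximum Feret diameter and Feret angle in [0°, 180°).
3. **Longitudinal statistics** — a repeated-measures linear mixed model
   on per-chip widths with saturated day × group means, a shared
   **unstructured covariance** across days (REML, direct likelihood on
   monotone-dropout series, Wald 95 % CIs), the *divergence day* = first
   day at which the two groups' CIs stop overlapping, and
   Kruskal–Wallis ANOVA with Dunn's tie-corrected post-hoc for the
   shape descriptors.

Because raw microscopy for such studies is rarely deposited, the
package ships seeded generators for all three input kinds — fluorescence
scenes with exact ground-truth edges, non-adjacent elliptical cell
masks with known shape parameters, and multivariate-normal cohorts with
a chosen covariance and dropout schedule — so the whole pipeline is
testable end to end.

## Worked example

```r
library(chipmorph)

# a narrowed day-10 lumen (true width 1023 µm) with blur and noise
sc <- generate_lumen_scene(
  scene_config(lumen_width_um = 1023, noise_sd = 0.07, blur_sigma = 1,
               seed = 11),
  chip_id = "chip07", day = 10L, group = "co-culture")
measure_image(sc$image)
#> <width_measurement> chip chip07 day 10: mean width 1023.62 um
#>   (148/148 valid profiles, threshold 0.4479)
```

The measured 1023.6 µm recovers the generator's ground truth within a
fraction of a pixel (3.25 µm) despite the noise.  The measurement keeps
every per-profile edge pair (`tidy()`) for audit, and `glance()` gives
the one-row per-chip summary.

```r
# the packaged reference cohort: 8 days, two groups, shared
# unstructured covariance, declining chip counts
co  <- generate_cohort(soc_cohort_design(seed = 42))
fit <- fit_lmm(co)
tidy(fit)
#> # A tibble: 16 × 7
#>     day group      estimate    se lower upper     n
#>   <int> <chr>         <dbl> <dbl> <dbl> <dbl> <int>
#> 1     2 co-culture    1296.  1.15 1294. 1298.    68
#> 2     2 control       1294.  2.63 1289. 1299.    13
#> 3     3 co-culture    1293.  1.33 1290. 1295.    68
#> ...
ci_divergence_day(fit)$first_divergence_day
#> [1] 6
```

Both groups start at the full ~1300 µm channel width; the co-culture
arm narrows over the culture period, and with this draw the groups'
95 % confidence intervals first fail to overlap on day 6 — the
divergence day.  `autoplot(fit)` shows the fitted trajectories with
their intervals.

```r
kruskal_dunn(data.frame(v = c(1, 2, 3, 4, 5, 6),
                        g = rep(c("a", "b", "c"), each = 2)), v, g)
#> <kw_dunn> Kruskal-Wallis H = 4.571 (df = 2, N = 6), p = 0.1017
```

`H = 4.571` is the textbook rank-sum value for these three groups of
two; pairwise Dunn z statistics and Bonferroni-adjusted p-values follow
in the printed table.

## Command line

A thin wrapper over the same functions lives in `inst/cli/chipmorph.R`:

```sh
Rscript inst/cli/chipmorph.R simulate-cohort --seed 3 --out cohort.csv
Rscript inst/cli/chipmorph.R stats-lmm --cohort cohort.csv --out out/
Rscript inst/cli/chipmorph.R measure-width --images imgs/ --out out/ \
    --correction-factor 1 --spacing 25 --margin 100
```

Every run writes its configuration, input checksums and per-stage
record counts into a `manifest.json` next to the outputs.

## Documentation

The methods vignette (`vignettes/chipmorph-methods.Rmd`) describes the
measurement model, the statistical assumptions, every tunable
parameter with its default and units, what the synthetic generators do
and do not emulate, and the package's numerical conventions.
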