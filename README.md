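# lensoct

Quantification of crystalline lens opacities from anterior segment OCT
(AS-OCT) B-scans.

AS-OCT images the lens in cross section; opacities show up as
hyper-reflective structures against the dark aqueous humour. Cataract in
Down syndrome is a motivating case: trisomy-21 lenses frequently carry
punctate cerulean "blue-dot" opacities scattered through the cortex that
conventional photograding summarises poorly, and quantifying them
requires counting and locating individual hyper-reflective dots, not just
grading an overall haze. `lensoct` is for vision scientists who have
B-scans plus region segmentations (nucleus, cortex, aqueous, PSC zone,
dot opacities) and want reproducible per-eye numbers and cohort
statistics out of them.

## The metrics

For a region of interest *R* and background *B*, with `I(p)` the pixel
intensity:

* **Pixel intensity ratio** — `PIR = mean(I(p), p ∈ R) / mean(I(p), p ∈ B)`.
  The nucleus is referenced to the aqueous humour (nuclear PIR); cortical,
  posterior subcapsular (PSC) and dot opacities are referenced to the
  entire opacity-free cortex.
* **Pixel area ratio** — `PAR = |opacity pixels| / |region pixels|`
  (cortex for cortical and dot opacity, PSC zone for PSC opacity).

Dots are identified as connected components (8-connectivity, minimum
2 px by default), counted, and classed central vs peripheral by whether
their centroid falls inside the central 4–4.5 mm window of the lens; an
opacity is a *true PSC* only within the central 3 mm. Eyes without a
given opacity class report 0 (not `NA`) for its PIR/PAR. LOCS III grade
records are validated (NO/NC on 0.1–6.9, C/P on 0.1–5.9) and flagged for
clinical significance at C ≥ 2.0, P ≥ 2.0, NO/NC ≥ 2.5. Group
comparisons use rank-sum tests (exact permutation p for small samples)
and Spearman associations.

Because no patient imaging is distributable, the package ships a seeded
phantom generator (`generate_scene()`, `generate_cohort()`) that renders
lens scenes with analytically known metrics, so the entire pipeline is
validated against exact ground truth.

## Worked example

```r
library(lensoct)
library(dplyr)

# a 512 x 1280 phantom: nuclear PIR 1.19, dot PIR 1.33, 12 dots, speckle CV 0.05
sp <- scene_spec(dot_count = 12, speckle_cv = 0.05, seed = 42)
sc <- generate_scene(sp)
m  <- quantify_eye(sc$image, sc$truth, central_width_mm = sp$central_width_mm)
glance(m)
#>   eye_id            nuclear_pir cortical_pir cortical_par psc_pir psc_par
#> 1 synthetic-seed-42        1.19            0            0       0       0
#>   dot_pir dot_par dot_count dot_count_central central_proportion
#> 1    1.33 0.00142        12                 8              0.667
```

The recovered nuclear PIR (1.19) and pooled dot PIR (1.33) match the
generator's analytic expectations despite 5% multiplicative speckle; the
cortical/PSC ratios are 0 because this phantom carries no areal opacity;
8 of the 12 dots have centroids inside the central 4.25 mm window.
`per_dot(m)` gives the per-dot profile (pixel count, centroid in mm,
offset from the lens axis, individual PIR).

Cohort-level, with the default 54 DS vs 46 control eyes:

```r
co <- generate_cohort(seed = 42)
build_group_table(co, "nuclear_pir")
#>   variable    group       n  mean    sd median    iqr   min   max     z        p
#> 1 nuclear_pir DS         54 1.20  0.0597  1.19  0.0753  1.09  1.34 -5.11  3.21e-7
#> 2 nuclear_pir control    46 1.25  0.0409  1.26  0.0599  1.17  1.35 -5.11  3.21e-7

ds <- filter(co, group == "DS")
spearman_assoc(ds$age_years, ds$nuclear_pir)
#>     rho             p     n
#> 1 0.710 0.00000000178    54
```

DS eyes show the lower nuclear PIR (z = −5.1) and the strong positive
age association (ρ = 0.71 in this replicate) that the generator encodes.
`autoplot(sc)` draws the phantom with its ground-truth dots;
`plot_cohort_variable(co, "nuclear_pir")` boxplots a metric by group.

For raw instrument data the entry points are `read_raw_scan()` (binary
dialect configurable via `raw_dialect()`), `resize_bicubic()` (512 × 512
→ 512 × 1280 display resolution), `compose_whole_lens()` (anterior +
posterior halves around an `NA`-sentinel gap), and
`read_label_mask()`/`segmentation_from_labels()` for TIFF/PNG region
masks.

## Conventions

Rows are axial depth (anterior up), columns lateral; indices are
1-based; the physical coordinate of column `c` is
`(c − 1) × lateral_scale` mm. Default display pitch is 0.0125 mm/column
(16 mm / 1280). The central window is half-open, `[−w/2, w/2)`, so a
4 mm window at display pitch is exactly 320 columns. See the vignette
(`vignettes/lens-opacity-quantification.Rmd`) for the full account of
model, conventions and limitations.
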