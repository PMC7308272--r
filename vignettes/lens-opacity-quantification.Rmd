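---
title: "Quantifying lens opacities from AS-OCT B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lens opacities from AS-OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lensoct)
library(dplyr)
```

## The measurement problem

Anterior segment OCT (AS-OCT) images the crystalline lens in cross
section: lens opacities appear as hyper-reflective structures against the
dark aqueous humour. `lensoct` quantifies those opacities with two simple,
dimensionless statistics computed over manually (or synthetically)
delineated regions:

* **Pixel intensity ratio (PIR)** — the mean intensity of a region of
  interest divided by the mean intensity of a background region. The
  nucleus is referenced to the aqueous humour (nuclear PIR); cortical,
  posterior subcapsular (PSC) and punctate "dot" opacities are referenced
  to the *entire opacity-free cortex*.
* **Pixel area ratio (PAR)** — the area of opacity pixels divided by the
  area of the lens region that contains them (the cortex for cortical and
  dot opacity, the PSC zone for PSC opacity).

Because both are ratios of means over co-registered pixels, they are
invariant to global illumination/gain changes (multiplying every pixel by
`c > 0` leaves every PIR unchanged, and PAR never looks at intensity at
all). Those invariances are enforced by the test suite.

Punctate dot opacities — the cerulean blue-dot class common in trisomy 21
lenses — are a separate layer from areal cortical/PSC opacity. They are
identified individually as connected components, counted, graded by pooled
PIR/PAR, and profiled radially: a dot is *central* when its centroid falls
inside the central 4–4.5 mm window of the lens, and an opacity counts as a
*true PSC* only when it lies within the central 3 mm. Keeping dots
distinct from areal opacity mirrors clinical practice, where an eye can
carry dozens of dots yet grade 0 for cortical cataract.

## Processing pipeline

1. **Ingestion** (`read_raw_scan()`): raw detector exports are headerless
   binary matrices; the shape, sample depth, byte order and memory layout
   are configurable (`raw_dialect()`, default 512 × 512, 8-bit,
   row-major) because the instrument's export format is unpublished. A
   payload/dialect size mismatch is an error, not a warning.
2. **Resizing** (`resize_bicubic()`): scans are brought to display
   resolution (512 × 1280) by separable cubic convolution with the Keys
   kernel, `a = -0.5` — the conventional "bicubic" of mainstream imaging
   stacks — with symmetric half-sample mirroring at the borders and no
   antialiasing prefilter (the canonical use is upsampling). Pixel-centre
   alignment makes same-shape resizing the identity; negative overshoot is
   clamped to 0; pixel pitch is rescaled so physical extent is preserved.
3. **Composition** (`compose_whole_lens()`): anterior and posterior
   acquisitions are stacked into a whole-lens image. Unimaged gap rows are
   `NA` sentinels, never zeros — a zero gap would silently drag down any
   background mean — and every statistic in the package skips them.
4. **Segmentation handling** (`lens_segmentation()`,
   `validate_segmentation()`, `label_dots()`, `central_region_mask()`):
   masks are validated for shape, disjointness (aqueous vs lens regions,
   nucleus vs cortex) and containment (dots inside the lens) before any
   metric is computed. Dot components can use 4- or 8-connectivity
   (default 8) and a minimum size (default 2 px, so single-pixel speckle
   outliers never count as dots). `detect_dots()` offers optional
   automation of the manual dot identification via a robust threshold,
   `median + k·mad` of the cortex distribution (median/MAD rather than
   mean/SD because the dots themselves contaminate the cortex sample).
5. **Quantification** (`quantify_eye()` and friends): one tidy row per
   eye with `nuclear_pir`, `cortical_pir/par`, `psc_pir/par`,
   `dot_pir/par`, `dot_count`, `dot_count_central` and
   `central_proportion`, plus a per-dot table via `per_dot()`.
6. **Grading and cohort statistics** (`validate_locs()`,
   `flag_clinical_significance()`, `grading_bias()`,
   `build_group_table()`, `rank_sum_compare()`, `spearman_assoc()`).

## Conventions and numerical choices

* **Zero means absent.** Eyes without quantifiable cortical, PSC or dot
  opacity report 0 for the corresponding PIR and PAR (not `NA`), matching
  how control eyes are tabulated; `central_proportion` alone is `NA` when
  there are no dots to locate.
* **PAR uses total opacity area.** The area ratio is the *total* opacity
  pixel count over the region pixel count. An alternative reading (mean
  per-component area over region area) exists, but total area is the
  quantity consistent with statements like "dots covered 0.2–14% of the
  cortex", and per-dot areas remain available in the per-dot table.
* **One background for all dots.** Dot PIR is referenced to the
  opacity-free cortex even for dots sitting in the nucleus, so per-eye dot
  grades are comparable across dot locations.
* **Nucleus mean excludes dot pixels.** Nuclear PIR measures nuclear
  opalescence; letting bright punctate opacities inflate it would conflate
  two distinct classes.
* **Half-open central window.** A column (or dot centroid) is central
  when its signed lateral offset from the axis lies in
  `[-w/2, w/2)`. With the 0.0125 mm/column display pitch, a 4 mm window
  selects exactly 320 columns; the inclusive alternative selects 321 and
  breaks the physical-width correspondence by one pixel. The central-width
  default is 4.25 mm, the midpoint of the 4–4.5 mm grading window, and is
  configurable within that range.
* **1-based indices.** Rows and columns are 1-based as usual in R; the
  physical coordinate of column `c` is `(c - 1) * lateral_scale` mm from
  the centre of the top-left pixel.
* **Exact decimal LOCS semantics.** LOCS III grades are one-decimal
  values; range checks and the clinical-significance thresholds
  (C ≥ 2.0, P ≥ 2.0, NO/NC ≥ 2.5, all inclusive) compare `round(10·g)`
  as integers so a floating 1.9999 can never masquerade as "just below
  2.0".
* **Exact small-sample rank tests.** `rank_sum_compare()` reports the
  tie-corrected standardized rank sum `z` always, and an *exact*
  two-sided permutation p-value (enumeration over all group assignments,
  in integer doubled-midrank arithmetic) whenever the combined sample is
  ≤ 16; the normal approximation takes over beyond that. Quantiles are
  type-7 (linear interpolation). No multiple-testing correction is
  applied by default, with Holm adjustment available as a flag.

## The synthetic phantom generator

No patient imaging is distributed with (or available to) this package, so
every pipeline stage is validated against seeded synthetic phantoms with
analytically known ground truth (`scene_spec()`, `generate_scene()`):

* **Geometry.** An elliptical lens (semi-axes capped at 4.5 × 2.25 mm)
  with a concentric nucleus at 60% of the lens semi-axes, a cortex band
  between them, aqueous filling the field above the lens, and a PSC zone
  defined as the posterior outer shell of the cortex within the central
  3 mm. This is the minimal geometry that reproduces the region topology
  the metrics depend on; it makes no attempt at anatomical realism
  (no cornea, iris or capsule rendering).
* **Intensities.** Default levels aqueous 100, cortex 105, nucleus 119
  and dots at 1.33 × cortex, i.e. nuclear PIR 1.19 and dot PIR 1.33 —
  the median/mean values reported for trisomy-21 lenses, inside the
  published ranges (nuclear PIR 1.10–1.45, dot PIR 1.14–1.68).
* **Dots.** 1–3 px radius disks placed by rejection sampling wholly
  inside the cortex, pairwise separated so they stay 8-disconnected; the
  number placed centrally is binomial with the target central fraction
  (default 0.468, i.e. 53.2% peripheral). Infeasible packings fail loudly
  after a bounded number of tries.
* **Noise.** Multiplicative i.i.d. gamma speckle with unit mean and
  CV = `speckle_cv` (default 0.05), the standard first-order OCT speckle
  approximation. Real OCT speckle is spatially correlated; i.i.d. noise is
  a stated simplification, which means recovery results here bound the
  *statistical* error of the ratio estimators, not segmentation error or
  correlated-noise effects on real scans.
* **Expected metrics are analytic.** They come from the spec levels and
  the placed dot table (`nucleus_level / aqueous_level`, total dot pixels
  over cortex pixels, ...), never from the rendered image — so
  noise-free scenes must reproduce them *exactly* (integer-level means
  are exact in double arithmetic), and noisy scenes must converge to them
  as `speckle_cv` shrinks. Both properties are tested.

`generate_cohort()` draws whole two-group cohorts (default 54 DS eyes vs
46 control eyes) at the summary level: truncated-normal ages (DS
24.1 ± 14.3 years on 6–55, controls 54.0 ± 3.4 on 50–60), nuclear PIR as
a linear age trend plus residual noise, dot opacity in 50% of DS eyes
with 1–50 dots (negative-binomial, mean ≈ 15.6), dot PIR 1.33 ± 0.12,
log-normal dot PAR clipped to 0.004–0.14, rare areal cortical/PSC events,
and LOCS III grades drawn per group and rounded to the 0.1 grid. The age
slope is derived from the target Spearman association (ρ ≈ 0.67 in DS,
0.28 in controls) using the *truncated* age SD, so the realized
correlation matches the target instead of being attenuated by the
recruitment window. Controls never carry cortical, PSC or dot opacity.
Records store their linear predictor (`nuclear_pir_expected`) for
recovery testing, and any record can be rendered into a full phantom via
`scene_spec_from_record()` — cohort replicates stay cheap because images
are only rendered on demand.

## Problem sizes used in the checks

The automated checks run phantoms of 96 × 192 to 128 × 256 pixels (the
pitch is rescaled so the field of view stays 16 × 8 mm) — region means
then pool thousands of pixels, which is what the ratio estimators care
about, and the full 512 × 1280 display geometry remains the default for
interactive use. The standing checks include: exact analytic agreement on
100 randomized noise-free scenes; PIR invariance (≤ 1e-9 relative) and
bit-identical PAR under 5 random intensity rescalings of 50 scenes; exact
dot-count/size recovery; mean recovered dot PIR within ±0.02 of 1.33 and
nuclear PIR within ±0.01 of 1.19 over 200 speckled scenes; bicubic output
within 1e-9 of a direct per-pixel convolution oracle; exact rank-sum
p-values against exhaustive permutation enumeration for all two-group
splits of n ≤ 10; a 16-row boundary truth table for clinical
significance; and ≥ 95% detection of the DS-vs-control nuclear PIR offset
at p < 0.05 over 100 cohort replicates.

## Known limitations

* Segmentation is assumed given (manual in practice); only the optional
  `detect_dots()` automates any delineation, and only for punctate dots.
* The phantom's i.i.d. speckle and idealized geometry mean passing tests
  demonstrate correctness of the *measurement arithmetic and its
  statistical behaviour*, not robustness to real-world segmentation
  error, motion artefact or correlated speckle.
* Raw-export intensity semantics (e.g. whether the instrument
  log-compresses amplitudes before export) are unknown; intensities are
  treated as given, which is safe for ratio comparisons within a
  consistent export pipeline but not across instruments.
* No DICOM support and no denoising; the dialect-based raw reader plus
  TIFF/PNG masks cover the intended workflow.
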