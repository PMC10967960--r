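# vitreoct

Quantification of vitreous immune cells from optical coherence
tomography (OCT) B-scan stacks.

Immune cells in the vitreous — hyalocytes and microglia/macrophage-like
cells — show up in OCT cross-sections as small hyperreflective opacities
above the bright retinal band. Their number, size, brightness and shape
track immune activation, which makes them a candidate non-invasive
biomarker of ocular inflammation (steroid-induced glaucoma models in
particular). `vitreoct` is for researchers who have such scans (or want
to validate an analysis of them) and need the computational pipeline:
layer segmentation, turbidity quantification, single-cell morphometry,
per-eye aggregation and cohort statistics — plus a synthetic phantom
generator with complete ground truth to prove the pipeline on.

## What it computes

For a stack of B-scans (rows = depth, columns = lateral position):

* **Layer segmentation** — per column, the inner limiting membrane (ILM)
  and the inner/outer retinal pigment epithelium (RPE) boundaries, from
  sustained transitions of the axial intensity profile plus CUSUM change
  points on ILM-aligned, laterally averaged profiles.
* **VIT/RPE relative intensity** — mean vitreous intensity over mean RPE
  intensity, per frame; the per-eye value is the mean over frames. A
  gain-invariant proxy for vitreous turbidity.
* **Opacity detection and morphometry** — vitreous pixels above a robust
  background threshold (median + k·σ_MAD, k = 6 by default) are grouped
  into connected components; each opacity gets an area
  (pixels × 3.815 µm²/px for the rodent protocol: 3 mm / 1536 px
  squared), mean intensity, and ellipse-of-inertia shape descriptors

      ecc = sqrt(1 − λ₂/λ₁),   θ = ½·atan2(2µ₁₁, µ₂₀ − µ₀₂),

  with eccentricity 0 for rounded/amoeboid somata and → 1 for elongated
  or flat ones, and orientation θ ∈ (−90°, 90°] against the horizontal.
* **Size-class taxonomy** — isolated cells (< 10 µm²), non-activated
  cells (10–50 µm²), activated cells (50–250 µm²), cell complexes
  (> 250 µm²); half-open, lower-inclusive intervals.
* **Cohort statistics** — Kolmogorov–Smirnov normality screen, one-way
  ANOVA across cohorts with Bonferroni-adjusted pairwise Welch tests,
  and lagged Pearson correlations (e.g. IOP at week 2 vs VIT/RPE at
  week 24), with weak/moderate/strong labels at |r| = 0.4 / 0.7.

See `vignettes/vitreoct-methods.Rmd` for the full model, parameter and
design discussion.

## Worked example

Generate a reduced-scale phantom with known ground truth, run the whole
pipeline on it, and score the result:

```r
library(vitreoct)

cfg <- phantom_config(height_px = 240, width_px = 360, n_frames = 3,
                      n_per_class = c(isolated = 4, non_activated = 6,
                                      activated = 5, complex = 3),
                      seed = 7)
ph <- generate_phantom(cfg)
ph$stack
#> <bscan_stack> 3 frame(s), 240 x 360 px, 3.815 um^2/px

segs <- lapply(seq_len(ph$stack$n_frames), function(f)
  segment_layers(ph$stack$frames[[f]], frame_index = f))
recs <- do.call(rbind, lapply(seq_len(ph$stack$n_frames), function(f) {
  fr <- ph$stack$frames[[f]]
  mask <- vitreous_mask(segs[[f]], dim(fr))
  detect_opacities(suppress_background(fr, mask), fr, frame_index = f,
                   min_area_px = 2)
}))
summarise_eye(recs, ph$stack$n_frames, vit_rpe = eye_vit_rpe(ph$stack, segs))
#> <eye_summary> 16 opacities over 3 frame(s); total 2334.8 um^2, mean 5.33/frame
#>   classes: isolated 12.5%, non_activated 37.5%, activated 31.2%, complex 18.8%
#>   VIT/RPE: 0.1263
```

16 opacities were detected across the 3 frames (5.33 per B-scan);
non-activated cells (10–50 µm²) are the largest population, and the
measured VIT/RPE turbidity 0.1263 sits close to the phantom's designed
0.12. Scoring against the generator's ground truth:

```r
end_to_end_recovery(cfg, min_area_px = 2)
#> <recovery_report>
#>   detection: 16/18 true blobs matched (recall 0.889, precision 1.000)
#>   feature errors: area 0.00 px, ecc 0.000, orientation 0.00 deg, intensity 0.0000
#>   class accuracy: 1.000
#>   VIT/RPE: measured 0.1263 vs designed 0.1200 (error +0.0063)
#>   boundary RMS (rows): ILM 0.53, RPE inner 0.84, RPE outer 0.75
```

The two unmatched "blobs" are single-pixel isolated cells excluded by
`min_area_px = 2` (the eligible-blob recall is 1.0); every matched
opacity has exact pixel-level area, shape and intensity agreement, and
the recovered layer boundaries are within a pixel of truth.

Real scans enter through `read_bscan_stack()` (multipage TIFF or a
directory of lossless frames; AVI exports must first be converted to a
lossless stack), and results leave through `write_feature_table()` /
`write_eye_summary()`. A thin command-line wrapper with
`info` / `simulate` / `analyze` subcommands is in
`inst/cli/vitreoct.R`.

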