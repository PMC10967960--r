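---
title: "Quantifying vitreous immunity from OCT B-scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vitreous immunity from OCT B-scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitreoct)
```

## The measurement problem

Immune cells resident in or recruited to the vitreous (hyalocytes and
microglia/macrophage-like cells) appear in OCT cross-sectional images as
small hyperreflective opacities floating in the dark vitreous above the
bright retinal band. Their number, size, shape and brightness change with
activation state, which makes them a candidate in-vivo biomarker of ocular
inflammation — in glaucoma models in particular. `vitreoct` implements the
computational half of that measurement: from a stack of B-scans it
produces, per eye and timepoint,

* the **VIT/RPE relative intensity** — mean vitreous intensity divided by
  mean intensity of the retinal pigment epithelium (RPE) band, a
  normalised turbidity proxy that cancels acquisition gain;
* a table of **hyperreflective opacities**, each with physical area,
  mean intensity, ellipse-of-inertia eccentricity and orientation, and a
  four-class size taxonomy: isolated cells (< 10 µm²), non-activated
  cells (10–50 µm²), activated cells (50–250 µm²), cell complexes
  (> 250 µm²);
* per-eye aggregates and a cohort statistics layer (Kolmogorov–Smirnov
  normality screen, one-way ANOVA with Bonferroni-adjusted pairwise Welch
  tests, lagged Pearson correlations between IOP and OCT measures).

The acquisition geometry it assumes by default is the rodent
posterior-pole protocol: 61 B-scans of 1536 × 496 pixels spanning 3 mm
laterally, hence a pixel pitch of 3000/1536 = 1.953 µm, a pixel area of
3.815 µm² and a frame area of 2.906 mm². The pixel area is nonetheless an
explicit parameter everywhere it enters a physical quantity.

## Layer segmentation

Each column of a B-scan is an axial intensity profile: dark vitreous,
then a bright retinal band terminating in the brighter RPE, then dark
tissue below. The segmenter proceeds in three passes per frame.

1. **ILM and rough outer boundary.** Profiles are smoothed with a small
   centred moving average (`axial_window`, default 5 rows) and classified
   against the midpoint of the vitreous and retina median intensities
   (the dark/bright split comes from Otsu's threshold on the smoothed
   frame). A transition counts only if sustained for `min_band_rows`
   (default 5) consecutive rows, so isolated speckle cannot fake a
   boundary. The outer boundary is the last row of the last sustained
   bright run. The ILM is the *start of the run that terminates at the
   outer boundary*, after bridging sub-threshold gaps shorter than
   `min_band_rows`: a bright opacity higher in the vitreous forms its own
   run and is ignored. (A naive "first sustained bright run" rule — the
   simplest reading of a threshold detector — was implemented first and
   rejected: exactly those opacities the pipeline exists to detect hijack
   it, displacing the ILM by tens of rows under realistic blob loads.)
2. **RPE band edges as change points.** The retina→RPE contrast is weak
   (≈ 1.3:1) relative to fully developed speckle, so per-column
   thresholding is hopeless at this boundary. Instead, profiles are
   aligned at a common anchor and averaged over a lateral window
   (`align_window`, default 31 columns — layer boundaries vary slowly
   across columns, so aligned averaging sharpens the step rather than
   blurring it). On the averaged profile the boundary is the change point
   maximising the CUSUM-scaled step contrast
   $\sqrt{n_1 n_2 / n}\,(\bar w_{right} - \bar w_{left})$, whose scaling
   equalises noise variance across candidate split points. The outer edge
   is estimated first (anchored at the rough outer boundary, window
   extended below it so the bright→dark step is interior); the inner edge
   is then estimated on ILM-anchored profiles *ending at the refined
   outer edge* — ending at the rough edge instead leaks blurred dark rows
   into the right-hand segment and biases the split towards the vitreous.
3. **Regularisation.** Columns where detection fails are filled by linear
   interpolation from neighbours; all three boundary curves are
   median-smoothed across columns (`smoothing_window`, default 15,
   forced odd); ordering `ilm < rpe_inner ≤ rpe_outer` is enforced.

A frame with no usable vitreous/retina contrast (separation of the two
medians below `min_contrast = 0.05`) raises a segmentation failure, as
does failure in half the columns. On clean piecewise-constant profiles
the recovered boundaries are exact; on speckled phantoms with curved
boundaries at ≥ 4:1 retina:vitreous contrast the RMS error of all three
boundaries is below 2 rows (typically < 1). Boundary recovery of the RPE
band degrades when the band is thinner than `min_band_rows`.

Row indices are 1-based, row 1 is the innermost vitreous, and `ilm_row`
is the first retinal row.

## VIT/RPE relative intensity

Per frame, the ratio of the mean intensity over the vitreous mask to the
mean over the RPE band (`rpe_inner_row`–`rpe_outer_row` inclusive); per
eye, the unweighted mean over frames. Two choices deserve note:

* The vitreous mask *includes* opacities. The ratio is a turbidity proxy
  validated against clinical vitreous haze, and cells are part of
  turbidity; excising them would also make the ratio depend on the
  detector's threshold.
* `margin_rows` (default 2) excludes a safety band immediately above the
  ILM, where partial-volume blending with the retina would otherwise
  leak into the vitreous mean; `top_margin_rows` (default 0) can exclude
  an acquisition-artefact band at the top of the frame.

Frames whose segmentation fails are excluded and reported, never
imputed. The ratio is exactly invariant under global intensity scaling
of a frame.

## Opacity detection and morphometry

**Background suppression.** Within the vitreous mask, a pixel is
foreground when it strictly exceeds `median + k_sigma × σ_MAD` of the
masked intensities (`k_sigma` default 6; `σ_MAD` the MAD-derived robust
standard deviation). Robust statistics make the threshold insensitive to
the opacities themselves, to bit depth and to overall gain. Under the
speckle model below, the per-pixel false-positive rate at `k_sigma = 6`
is ≈ 2.5 × 10⁻⁴ — negligible for components of ≥ 2 pixels, which is why
analyses aimed at detection fidelity use `min_area_px = 2`, while the
default `min_area_px = 1` keeps single-pixel isolated cells (3.815 µm²)
reportable when counting statistics matter more than per-object purity.

**Components and features.** Connected components (8-neighbour by
default, so diagonally touching speckle of one cell does not split it;
4-neighbour available) are labelled by a sparse union-find pass. Each
component of at least `min_area_px` pixels yields one record:
`area_px`, `area_um2 = area_px × pixel_area_um2` (exactly), centroid,
mean intensity over the original frame, and shape descriptors from the
ellipse of inertia of the pixel set: with second central moments
$\mu_{20}, \mu_{02}, \mu_{11}$ and eigenvalues $\lambda_1 \ge \lambda_2$,

$$\mathrm{ecc} = \sqrt{1 - \lambda_2/\lambda_1}, \qquad
\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11},\ \mu_{20}-\mu_{02}),$$

with $\theta$ in degrees on (−90°, 90°], positive counter-clockwise from
the image horizontal (the row axis is negated so that "up" is positive).
A single pixel, or any isotropic pixel set, has eccentricity 0 and
orientation 0 by convention. A filled disc measures ecc ≈ 0; a 1 × n
line measures ecc → 1 at orientation 0°; a filled ellipse with 2:1 axes
measures ecc = √3/2 ≈ 0.866 regardless of rotation.

**Size classes** use half-open, lower-inclusive intervals [0, 10),
[10, 50), [50, 250), [250, ∞) µm². A boundary area such as exactly
10 µm² therefore joins the upper class; with the default pixel area no
attainable pixel count lands exactly on a boundary, so the rule is
mostly a matter of definition hygiene.

**Per-eye aggregation** produces total area, mean opacities per B-scan,
mean area overall and per class, class percentages (summing to 100 when
any opacity exists), and per-class mean eccentricity, intensity and
orientation. The orientation mean is the *signed arithmetic* mean, not a
circular mean: opposing orientations are meant to cancel towards 0,
which is precisely the behaviour used to read directed versus dispersed
cell motility.

No linking of opacities across adjacent B-scans or across visits is
attempted; the analysis is strictly 2-D per cross-section.

## Cohort statistics

* `normality_test`: one-sample KS statistic against a normal with the
  sample mean and SD. This is the plain KS screen (no Lilliefors
  correction for estimated parameters); it is deliberately the simple,
  stated procedure, used as a screen rather than an inferential
  endpoint.
* `groupwise_anova`: one-way ANOVA per measure and week across cohorts
  (MsDx, MsDxF, control), each (animal, eye, week) row one observation
  — eyes are not modelled as repeated measures, which matches how the
  cohort tables are assembled and is stated rather than hidden. Pairwise
  comparisons are Welch t-tests (robust to the unequal group sizes typical
  of longitudinal attrition) with Bonferroni adjustment
  `p_adj = min(1, m·p)`. On two groups the ANOVA F equals the squared
  pooled t.
* `lagged_correlations`: Pearson r between measure X at week `w_x` and
  measure Y at week `w_y`, paired within (animal, eye), with optional
  cohort/sex/eye filters; requires ≥ 3 pairs and non-zero variance.
  Strength labels follow the |r| < 0.4 / 0.4–0.7 / > 0.7 convention
  (weak / moderate / strong), signed direct/inverse — a labelling
  convention, not an inferential claim.

The study week grid is {0, 2, 4, 6, 8, 12, 18, 24}.

## The synthetic phantom

Real cohort scans are not publicly deposited, so validation rests on a
generator with complete ground truth. A phantom frame is built as

1. base intensities along sinusoidally curved boundaries (phase advances
   across frames): dark vitreous, retinal band, RPE band, dark below;
   the vitreous base intensity is `vit_rpe_design × rpe_intensity`, so
   the designed ratio is explicit;
2. multiplicative mean-one gamma speckle (shape 4, a standard
   fully-developed-speckle surrogate for OCT; exposed as a parameter);
3. elliptical blobs rasterised from pixel centres, placed in the
   vitreous by rejection sampling with a one-pixel exclusion moat so
   components never merge; blob intensity is *added* on top of the local
   speckled background, parameterised as a contrast multiple of the
   designed background median so detection-threshold analyses are
   well-posed;
4. clamping to [0, 1] and quantisation to the 16-bit grid, so that
   lossless 16-bit TIFF round-trips are bit-identical.

Ground truth records **post-rasterisation** values — pixel count,
moment-based eccentricity/orientation of the actual pixel set, mean
intensity measured on the rendered frame — so feature-recovery tests are
exact rather than rasterisation-limited. Default intensities are
vitreous 0.066, retina 0.42, RPE 0.55, below-RPE 0.03, designed VIT/RPE
0.12. The RPE level is kept moderate on purpose: with mean-one gamma
speckle, values clipped at 1.0 would otherwise bias the measured RPE
mean low and the recovered ratio high; at 0.55 the clipping bias on a
0.12 ratio is ≈ 0.003, well inside the ±0.01 recovery band the phantom
is designed to support.

What the phantom does **not** emulate: the OCT point-spread function,
depth-dependent attenuation and shadowing under opacities, motion and
registration artefacts, intra-retinal layering, or spatially varying
vitreous texture. Passing phantom recovery therefore demonstrates that
the *computational* pipeline is correct and calibrated under its stated
noise model — not that segmentation is robust to every pathology of real
acquisitions.

`end_to_end_recovery()` chains generation → segmentation → suppression →
detection → aggregation and scores detection recall/precision (matching
by pixel overlap), per-feature errors on matches, the size-class
confusion matrix, VIT/RPE error against design, and boundary RMS. Recall
is reported both over all ground-truth blobs and over "eligible" blobs
(`area_px ≥ min_area_px`), since sub-threshold singletons are excluded
by construction, not missed.

## Numerical choices and degenerate inputs

* Intensities are normalised to [0, 1] on read (dividing by the
  container's maximum representable value), so every threshold in the
  package is bit-depth independent.
* Greyscale conversion of colour frames is the unweighted channel mean —
  reproducible and codec-independent, unlike luma weightings.
* Constant masked regions give an all-false foreground (MAD = 0 and the
  strict inequality), not an error; uniform frames fail segmentation
  with an explicit error; zero detected opacities give zero aggregates
  with percentages 0 and a flag, not NaNs.
* Ties in the change-point objective resolve to the first maximum
  (deterministic); component labels are assigned in column-major scan
  order; the generator restores the caller's RNG state.
* AVI containers are refused with guidance: no lossless video decoder is
  available to R here, and lossy decoding would perturb exactly the
  pixel statistics the thresholds depend on. Lossless TIFF/PNG stacks
  are the supported interchange.

## Problem sizes used in validation

The test-suite and acceptance phantoms run at 240 × 360 pixels and 2–4
frames with 15–40 blobs — large enough that every mechanism (curvature,
speckle, class mix, boundary refinement windows) operates at realistic
ratios, while keeping the whole suite fast enough to run routinely. The
full-protocol geometry (496 × 1536 × 61) is the generator default and
runs identically, just slower; nothing in the pipeline depends on the
reduced size.

## Known limitations

* The RPE inner boundary needs a band at least `min_band_rows` thick and
  benefits from slowly varying boundaries; pathologically distorted
  retinas would call for a different segmenter.
* The KS screen with estimated parameters is anti-conservative in
  principle; treat it as a screen.
* Orientation of near-circular opacities (ecc ≲ 0.3) is numerically
  ill-conditioned, as the equivariance analysis shows; downstream
  interpretation should weight orientation by eccentricity.
* Single-pixel opacities carry no shape information (ecc = 0 by
  convention) yet dominate the isolated-cell class; their counts are
  threshold-sensitive in a way larger classes are not.
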