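---
title: "CSF-system biomarkers and cortical protein aggregation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSF-system biomarkers and cortical protein aggregation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ventmark` implements an end-to-end analysis linking three cerebrospinal-fluid
(CSF) system markers — lateral-ventricle volume (VV), choroid plexus volume
(CPV) and ventricular PET radioactivity (VR, an indirect proxy of
choroid-plexus-related clearance) — to cortical amyloid and tau load measured
by PET. Because the cohort data this kind of study uses are not public, the
package ships a first-class synthetic-data generator: a linear-Gaussian
structural-equation cohort plus per-participant 3D phantoms from which every
biomarker is re-extracted by the same image pipeline a real study would use.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic conditions can and cannot show.

## The synthetic cohort

The cohort is drawn from a structural-equation model (SEM) over standardized
latent nodes ordered CPV → VR → VV → Aβ → tau:

* CPV → VR negative (larger plexus, lower ventricular tracer activity),
* VR → VV negative and CPV → VV positive,
* VV → Aβ and CPV → Aβ positive,
* Aβ → tau positive, plus a small positive VV → tau edge.

Each node is its stage shift plus the coefficient-weighted sum of its parents
plus Gaussian noise. Disease stage (CU(Y), A−T−, A+T−, A−T+, A+T+; group
sizes 52/166/64/4/92, total 378) enters as additive location shifts on CPV,
VV, Aβ and tau; VR inherits stage effects only through CPV. Latents are then
mapped to physical units: volumes are log-normal around 22 000 mm³ (VV) and
1600 mm³ (CPV) with a mild intracranial-volume (ICV) factor, PET values are
linear maps onto the SUVR scale. Covariates (age, sex, APOE4, ICV) are drawn
per stage from plausible adult distributions.

Edge coefficients and stage shifts were **calibrated once, by simulation**,
against three kinds of targets, and are fixed defaults thereafter:

1. the cohort-level, ICV-residualized Spearman correlations
   ρ(CPV,VV) ≈ 0.74, ρ(VV,VR) ≈ −0.71, ρ(CPV,VR) ≈ −0.62;
2. amyloid group means ordered CU(Y) ≈ A−T− < A+T− < A+T+, with VV Z-scores
   (against the young-control reference) rising strictly along the stages;
3. the conditional-independence headline: VV predicts tau only through Aβ,
   so the adjusted VV → tau effect is null-centred.

Target (3) constrains the generator more than is obvious. If the tau group
means are forced to a pattern in which the amyloid-positive/tau-negative
group sits at high Aβ but low tau while the A+T+ group sits at high Aβ, high
tau *and* higher VV, then — at equal Aβ — VV predicts tau by construction and
no choice of stage shifts removes the artifact. The defaults therefore
(a) separate the Aβ distributions of A+T− and A+T+ (means ≈ 1.85 and 2.60
SUVR) so conditioning on Aβ absorbs most of the tau-status information,
(b) keep the VV shift gap between those two groups modest (0.45 vs 0.72),
and (c) use a realistic, heavy within-group tau noise (≈ 0.55 SUVR within
group, of the order seen in tau-positive patient groups). The
resulting tau group means (≈ 0.89/0.92/1.05/2.9/1.95 SUVR) are deliberately
synthetic values, not transcriptions of any published table; they preserve
positivity ordering around the 1.18 cutoff.

Stage effects are additive location shifts, not interactions, and all noise
is Gaussian — the simplest structure consistent with the qualitative group
patterns. The A−T+ group (n = 4) is generated but flagged: group comparisons
involving groups with n < 5 warn rather than fail.

## Phantoms

`simulate_phantom()` realizes each participant as a 96³ label volume at 2 mm
isotropic resolution (configurable): an intracranial ellipsoid sized from the
participant's ICV with a 1-voxel meningeal rim; a ~3-voxel cortical ribbon
split into sector labels standing in for the neocortical amyloid composite
and the temporal tau meta-region (the mapping is geometric, not anatomically
faithful); an inferior-posterior cerebellar blob serving as the reference
region; white matter; two lateral ventricles (posterior body plus a narrower
anterior frontal horn); and choroid plexus blobs inside the ventricle bodies.

Two numerical choices matter:

* The ventricle shape is scaled by bisection until its voxel count matches
  the target volume; the achieved error is bounded by the count jump at the
  bisection point, in practice ≤ 2 %. The body's anterior–posterior extent is
  fixed (growth is lateral and vertical) and the body sits posterior enough
  that the anterior third of the ventricles' y-extent — the region the
  Evans' Index measures — always contains only the horn.
* The choroid blobs are selected by *ranking* ventricle voxels on the plexus
  ellipsoids' quadratic form and taking exactly the target count, making the
  extracted plexus volume correct to one voxel (bisection on the blob scale
  can jump several voxels at once and was observed to miss by > 10 % for
  small blobs).

PET volumes are piecewise-constant tissue means plus Gaussian noise
(SD 0.05 SUVR by default). Means are chosen so that, *before* smoothing, the
composite SUVRs recover the participant's latent Aβ/tau values and the
ventricular mask recovers the latent VR values to within a few thousandths.
After the default 8 mm smoothing the 6 mm cortical ribbon suffers heavy
partial-volume dilution — a deliberate property of the phantom, mirroring
real PET, which is why recovery contracts are stated pre-smoothing.

What the phantoms do **not** model: cortical folding, registration error,
scanner noise spectra, partial-volume physics beyond the geometric dilution
above, and tracer kinetics. Passing tests therefore demonstrate the
correctness of the measurement and inference machinery under known truth,
not performance on real images.

## Image-derived biomarkers

* **Volumes** are voxel counts times voxel volume; ICV is all non-background
  voxels. VV and CPV are residualized on ICV by OLS before Z-scoring and
  correlation, with the regression fitted on all included participants
  (including the young controls).
* **Evans' Index** is the maximal left–right extent of ventricle voxels over
  axial slices, restricted to the anterior third of the ventricles' own
  anterior–posterior extent, divided by the maximal left–right extent of the
  head interior. Width on a slice is `(max x − min x + 1) × voxel size`; no
  sub-voxel interpolation. The skull diameter is global by default; a
  `same_slice` flag measures it on the horn's slice instead. Exclusion is
  strict (`EI > 0.3`).
* **SUVR**: meninges are zeroed *before* smoothing (preventing meningeal
  spill-in), then volumes are smoothed to 8 mm FWHM (separable Gaussian,
  reflective boundaries; the kernel is truncated at 4σ and renormalized, so
  constants are preserved exactly and the global mean to ~10⁻⁴ relative).
  Composite SUVRs are volume-weighted means over member labels divided by
  the cerebellar reference mean; the phantom uses a single cerebellar
  compartment for both the amyloid (full cerebellum) and tau (inferior
  cerebellum) references.
* **Ventricular radioactivity**: ventricles minus choroid plexus, eroded by
  a ball of radius `round(erosion_mm / voxel size)` voxels (default 2 mm),
  then SUVR against the tracer's reference region. Whether VR is computed
  before or after smoothing is a flag (`vr_presmoothing`), defaulting to
  after.
* **A/T staging** uses strict thresholds: amyloid-positive iff neocortical
  SUVR > 1.55, tau-positive iff temporal meta-region SUVR > 1.18; ties are
  negative.

## Cohort statistics

Z-scores are normalized by the mean and SD of the young-control reference.
Group comparisons use a classical one-way ANOVA followed by Tukey HSD
pairwise tests, with Benjamini–Hochberg step-up correction applied *across
the pairwise family* at q = 0.05 — applying both Tukey and FDR is unusual
but mirrors the analysis this package reproduces; both p-values are
reported. The FDR family defaults to per-outcome scope. Spearman
correlations use average ranks and the large-sample t approximation for
p-values. `ols_standardized()` scales continuous variables to unit SD and
centres binary (0/1) variables without scaling, so "standardized beta" means
per-SD for continuous and per-category for binary covariates; covariates are
always fitted but reported separately. Covariate profiles `cov1`
(age/sex/APOE4), `cov2` (+ICV) and `cov3` (+grey-matter volume) mirror the
analysis variants.

## Voxel-wise inference

`fit_voxelwise()` fits, per in-mask voxel, an OLS model of the participant
PET volumes on a shared design matrix and returns the contrast t-map.
Degenerate voxels (zero residual variance) are flagged: constant outcomes
get t = 0, exact fits are capped at ±10⁶. Smoothness is estimated from the
unit-normalized residual images via the variance of their spatial
derivatives (per-axis FWHM = √(4 ln 2 / λ)), not assumed from the nominal
kernel; a `fwhm_mm` argument allows the nominal value instead.

The family-wise threshold solves the expected-Euler-characteristic equation
for a 3D t-field (EC densities for d = 0…3, Worsley-style), summed over
resel counts. Lower-dimensional resel counts are approximated by an
equivalent cuboid with the mask's bounding-box aspect ratio and its exact
volume. The threshold is two-sided (each tail gets α/2). The corrected level
α = 0.001 is treated as the random-field-theory level, the primary mode;
`mode = "voxel-fdr"` provides a voxel-wise BH alternative because the two
descriptions of the correction circulate for this analysis and the package
does not adjudicate between them.

Monte-Carlo calibration (part of the test suite) simulates null smooth
fields at FWHM 8 mm on a 32³ grid. The fields are sampled at 1.5 mm and
smoothed on a padded grid that is cropped afterwards, so the lattice field
approximates the continuum random field the theory describes: at 2 mm
sampling the empirical family-wise error is ≈ 0.02 (the known conservatism
of continuum RFT for discretely sampled t-maxima), at 1.5 mm it is ≈ 0.045
at a nominal 0.05. Problem sizes (200 replicates, n = 40 regressions) were
chosen as the smallest giving stable proportions.

## Sequential mediation

A path model is an ordered DAG of standardized regressions: each node is
regressed on its declared parents plus the covariates. Indirect effects are
products of edge coefficients along every directed path of length ≥ 2 into
the terminal outcome. Inference uses bias-corrected (BC, not BCa — no
acceleration term) bootstrap percentile intervals over participant
resamples: z₀ is the normal quantile of the fraction of bootstrap estimates
below the point estimate, and the interval endpoints are the bootstrap
quantiles at Φ(2z₀ ± z₁₋α/₂). Significance is "CI excludes zero".
Missing data are handled by complete-case analysis; resampling is of whole
participant rows, preserving the covariate joint distribution; resamples
with rank-deficient node regressions are rejected and redrawn (warned above
5 %). The default is 10 000 iterations; simulation studies in the tests use
500 with the documented `n_boot` argument. Two published topologies ship as
presets, named by their terminal outcome: `path_preset("amyloid")`
(CPV/VR → VV → Aβ) and `path_preset("tau")` (extending to tau with Aβ as the
downstream mediator). The published diagrams disagree on the direction
between VR and VV across their two panels; both variants are expressible by
re-declaring edges and the package keeps the VR → VV orientation in its
presets without adjudicating.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → extract → exclude → stage → group stats →
(voxel-wise) → mediation, writing CSV/JSON/NIfTI outputs and a manifest with
per-stage seeds derived from one master seed by stable hashing, so each
stage is individually reproducible and identical configurations give
identical tables. This package is a library, not a shell tool: the exported
functions and this vignette are its interface.

## Known limitations

* The generator's group means and covariate distributions are synthetic
  choices documented above, not estimates of any real cohort.
* Phantom geometry is convex and smooth; Evans' Index behaviour on highly
  irregular ventricles is untested by construction.
* RFT assumes stationary smoothness; the resel approximation for non-box
  masks is an equivalent-cuboid heuristic.
* The mediation model is linear with Gaussian errors and makes no causal
  identification claims beyond its own path framing.
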