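# ventmark

Ventricular and choroid plexus biomarkers from synthetic brain phantoms:
an end-to-end, testable re-implementation of an analysis linking the
cerebrospinal-fluid (CSF) system to cortical protein aggregation in the
Alzheimer's disease spectrum.

## The scientific problem

Three image-derived markers describe the CSF system: lateral-ventricle
volume (**VV**, CSF-space enlargement), choroid plexus volume (**CPV**,
secretory tissue morphology), and ventricular PET radioactivity (**VR**,
non-specific tracer signal inside the ventricles, an indirect proxy of
choroid-plexus-related clearance). The analysis asks how these relate to
neocortical amyloid (Aβ) and temporal-meta-region tau load measured by PET,
across biomarker stages A∓T∓ defined by SUVR cutoffs (Aβ > 1.55,
tau > 1.18), in participants screened for disproportionate ventriculomegaly
by the Evans' Index (excluded when EI > 0.3).

The statistical core:

* per-participant quantification — region volumes and ICV residualization,
  EI = max frontal-horn width / internal skull diameter, meninges-masked
  8 mm-smoothed SUVR with cerebellar reference regions, and an eroded,
  plexus-free ventricular mask for VR;
* cohort statistics — Z-scores against a young-control reference, one-way
  ANOVA with Tukey HSD and Benjamini–Hochberg FDR, Spearman correlations,
  standardized multivariable OLS;
* voxel-wise linear models with random-field-theory (RFT) corrected t-map
  thresholds, with smoothness estimated from residuals
  (FWHM = √(4 ln 2 / λ), expected-Euler-characteristic threshold);
* sequential mediation over the path diagram CPV → VR → VV → Aβ → tau:
  indirect effects as products of standardized path coefficients, tested by
  bias-corrected bootstrap confidence intervals (default 10 000 draws).

Because the motivating cohort is not public, the package generates its own
study conditions: a linear-Gaussian structural-equation cohort
(n = 378; groups 52/166/64/4/92) and, per participant, a 3D phantom (label
volume plus amyloid- and tau-PET SUVR volumes, NIfTI-compatible) from which
every biomarker above is re-extracted by the same code path a real study
would use. See `vignettes/ventmark-methods.Rmd` for the models, calibration
and limitations.

## A worked example

```r
library(ventmark)

spec   <- default_params()                   # calibrated SEM, n = 378
cohort <- simulate_cohort(spec, seed = 42)

# realize one A+T+ participant as a 96^3 phantom and quantify it
rec <- cohort[cohort$stage == "A+T+", ][1, ]
ph  <- simulate_phantom(rec, grid_spec(), seed = 7)
extract_biomarkers(ph, fwhm_mm = 0)[, c("vv", "cpv", "ei",
                                        "abeta_neocortex", "stage")]
#>    vv  cpv     ei abeta_neocortex stage
#> 91992 2136 0.2963           2.929  A+T+
# ground truth: vv 92008 mm^3, cpv 2138 mm^3, abeta 2.929 SUVR

# cohort-level associations (ICV-residualized)
cohort$vv_resid  <- residualize(cohort$latent_vv,  cohort$icv)
cohort$cpv_resid <- residualize(cohort$latent_cpv, cohort$icv)
spearman_cor(cohort$cpv_resid, cohort$vv_resid)$rho
#> 0.747

cohort$abeta_neocortex <- cohort$latent_abeta
ols_standardized(cohort, "abeta_neocortex", c("cpv_resid", "vv_resid"),
                 c("age", "sex", "apoe4", "icv"))
#> Standardized OLS (n = 378, R^2 = 0.508)
#>           beta_std   ci_lo  ci_hi        p      role
#> cpv_resid  0.14238  0.0416 0.2432 5.77e-03 predictor
#> vv_resid   0.54269  0.4398 0.6456 2.62e-22 predictor
#> ...

# sequential mediation with bias-corrected bootstrap CIs
cohort$vr_amyloid <- cohort$latent_vr_amyloid
med <- bootstrap_ci(cohort, path_preset("amyloid", n_boot = 1000, seed = 3))
med$indirect[, c("path", "estimate", "ci_lo", "ci_hi", "significant")]
#>                                          path estimate   ci_lo   ci_hi significant
#>  cpv_resid>vr_amyloid>vv_resid>abeta_neocortex  0.1274  0.0948  0.1658        TRUE
#>           cpv_resid>vr_amyloid>abeta_neocortex -0.0453 -0.1027  0.0167       FALSE
#>             cpv_resid>vv_resid>abeta_neocortex  0.2588  0.1972  0.3296        TRUE
#>            vr_amyloid>vv_resid>abeta_neocortex -0.2140 -0.2759 -0.1643        TRUE
```

Both volumes independently predict amyloid with VV dominating, and the
CPV/VR effects on Aβ run through VV — the qualitative headline the package
is calibrated to reproduce. `run_pipeline(pipeline_config(...))` chains the
whole flow (simulate → extract → EI exclusion → staging → statistics →
mediation) with per-stage seeds and a run manifest.

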