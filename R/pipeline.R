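# End-to-end pipeline: simulate -> extract -> exclude -> stage -> analyze

#' Pipeline configuration
#'
#' @param sem a [sem_spec()]; default [default_params()].
#' @param grid a [grid_spec()].
#' @param stages which pipeline stages to run, a prefix of
#'   `c("simulate", "extract", "exclude", "stage", "group_stats",
#'   "voxelwise", "mediation")`.
#' @param ei_threshold Evans' Index exclusion threshold (default 0.3).
#' @param a_cut,t_cut A/T staging cutoffs (defaults 1.55, 1.18).
#' @param fwhm_mm PET smoothing target in mm (default 8).
#' @param erosion_mm VR-mask erosion in mm (default 2).
#' @param alpha_voxel voxel-wise corrected level (default 0.001).
#' @param n_boot mediation bootstrap iterations (default 10000).
#' @param covariates covariate profile name for the analyses
#'   (see [covariate_profile()]).
#' @param pet_noise_sd phantom PET noise SD.
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(sem = default_params(), grid = grid_spec(),
                            stages = c("simulate", "extract", "exclude",
                                       "stage", "group_stats", "mediation"),
                            ei_threshold = 0.3, a_cut = 1.55, t_cut = 1.18,
                            fwhm_mm = 8, erosion_mm = 2, alpha_voxel = 0.001,
                            n_boot = 10000L, covariates = "cov2",
                            pet_noise_sd = 0.05,
                            out_dir = tempfile("ventmark_run_"), seed = 1L) {
  order_ <- c("simulate", "extract", "exclude", "stage", "group_stats",
              "voxelwise", "mediation")
  if (!all(stages %in% order_)) stop("unknown stage name")
  if (any(c(ei_threshold, a_cut, t_cut) <= 0)) stop("thresholds must be positive")
  structure(list(sem = sem, grid = grid, stages = stages,
                 ei_threshold = ei_threshold, a_cut = a_cut, t_cut = t_cut,
                 fwhm_mm = fwhm_mm, erosion_mm = erosion_mm,
                 alpha_voxel = alpha_voxel, n_boot = as.integer(n_boot),
                 covariates = covariates, pet_noise_sd = pet_noise_sd,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort and phantoms, extracts image-derived biomarkers,
#' applies the Evans' Index exclusion, assigns A/T stages from the
#' extracted SUVRs, and runs the group statistics, optional voxel-wise
#' t-map and mediation analyses. All tables are written as CSV, analysis
#' summaries as JSON, and t-maps as NIfTI under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return A `run_manifest`: per-stage seeds and output files, counts
#'   (simulated / excluded / retained), and the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  seeds <- list()
  results <- list()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  # simulate --------------------------------------------------------------
  seeds$simulate <- derive_seed(config$seed, 1L)
  cohort <- simulate_cohort(config$sem, seed = seeds$simulate)
  emit(cohort, "cohort_truth.csv")
  n_sim <- nrow(cohort)
  phantoms <- NULL
  biomarkers <- NULL

  if ("extract" %in% config$stages) {
    seeds$extract <- derive_seed(config$seed, 2L)
    phantoms <- simulate_phantoms(cohort, config$grid, seed = seeds$extract,
                                  noise_sd = config$pet_noise_sd)
    biomarkers <- do.call(rbind, lapply(phantoms, extract_biomarkers,
                                        fwhm_mm = config$fwhm_mm,
                                        erosion_mm = config$erosion_mm,
                                        a_cut = config$a_cut,
                                        t_cut = config$t_cut))
    rownames(biomarkers) <- NULL
  }

  n_excluded <- 0L
  if (!is.null(biomarkers) && "exclude" %in% config$stages) {
    drop <- biomarkers$ei > config$ei_threshold
    n_excluded <- sum(drop)
    report <- data.frame(id = biomarkers$id[drop], ei = biomarkers$ei[drop])
    emit(report, "ei_exclusions.csv")
    biomarkers <- biomarkers[!drop, , drop = FALSE]
    cohort <- cohort[cohort$id %in% biomarkers$id, , drop = FALSE]
    phantoms <- phantoms[biomarkers$id]
  }

  if (!is.null(biomarkers)) {
    # merge covariates, residualize volumes against ICV
    biomarkers <- merge(biomarkers,
                        cohort[, c("id", "stage", "age", "sex", "apoe4")],
                        by = "id", sort = FALSE)
    names(biomarkers)[names(biomarkers) == "stage.x"] <- "stage_extracted"
    names(biomarkers)[names(biomarkers) == "stage.y"] <- "stage"
    biomarkers$vv_resid <- residualize(biomarkers$vv, biomarkers$icv)
    biomarkers$cpv_resid <- residualize(biomarkers$cpv, biomarkers$icv)
    emit(biomarkers, "biomarkers.csv")
    results$biomarkers <- biomarkers
  }

  if (!is.null(biomarkers) && "group_stats" %in% config$stages) {
    ref <- biomarkers$stage == "CU(Y)"
    z <- data.frame(
      id = biomarkers$id, stage = biomarkers$stage,
      vv_z = zscores_vs_reference(biomarkers$vv_resid, ref),
      cpv_z = zscores_vs_reference(biomarkers$cpv_resid, ref),
      vr_amyloid_z = zscores_vs_reference(biomarkers$vr_amyloid, ref))
    emit(z, "zscores.csv")
    gc_vv <- withCallingHandlers(
      oneway_anova_tukey(biomarkers$vv_resid, biomarkers$stage),
      warning = function(w) invokeRestart("muffleWarning"))
    results$anova_vv <- gc_vv
    emit(gc_vv$pairwise, "anova_vv_pairwise.csv")
    results$zscores <- z
  }

  if (!is.null(biomarkers) && "voxelwise" %in% config$stages) {
    covs <- covariate_profile(config$covariates)
    design <- design_matrix(biomarkers, "vv_resid", covs)
    vols <- lapply(phantoms, function(p)
      smooth_to_fwhm(mask_meninges(p$amyloid, p$labels), config$fwhm_mm))
    mask <- label_mask(phantoms[[1]]$labels,
                       c("neocortex_composite", "meta_temporal", "grey_matter"))
    tm <- fit_voxelwise(vols, design, mask)
    tm <- rft_threshold(tm, alpha = config$alpha_voxel)
    tmap_path <- file.path(config$out_dir, "tmap_vv_amyloid.nii.gz")
    write_volume(tm$tmap, tmap_path)
    files <- c(files, tmap_path)
    results$tmap <- tm
  }

  if (!is.null(biomarkers) && "mediation" %in% config$stages) {
    seeds$mediation <- derive_seed(config$seed, 7L)
    spec_m <- path_preset("tau", n_boot = config$n_boot,
                          seed = seeds$mediation)
    med <- bootstrap_ci(biomarkers, spec_m)
    results$mediation <- med
    med_path <- file.path(config$out_dir, "mediation.json")
    jsonlite::write_json(list(indirect = med$indirect, direct = med$direct,
                              n = med$n, n_boot = med$n_boot_used),
                         med_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, med_path)
  }

  manifest <- structure(list(
    config_hash = digest_config(config),
    seeds = seeds, files = files,
    counts = c(simulated = n_sim, excluded = n_excluded,
               retained = n_sim - n_excluded),
    version = as.character(utils::packageVersion("ventmark")),
    results = results), class = "run_manifest")
  jsonlite::write_json(
    list(config_hash = manifest$config_hash, seeds = seeds,
         files = basename(files), counts = as.list(manifest$counts),
         version = manifest$version),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  manifest
}

# order-stable hash of the configuration (no external digest dependency)
digest_config <- function(config) {
  s <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")])), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% .Machine$integer.max)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n  counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  cat("  files:", length(x$files), "written\n")
  invisible(x)
}
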