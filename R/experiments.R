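#' Run a scripted end-to-end experiment
#'
#' Orchestrates the toolkit's validation arms end to end and writes all
#' artifacts plus a JSON manifest (package version, seeds, parameters,
#' metrics, artifact paths).  Deterministic stages reproduce bit-identical
#' metrics when rerun with the same configuration.
#'
#' Experiments:
#' \describe{
#'   \item{gel_targeting}{seeded gel-phantom targeting runs; writes
#'     `report.json` with per-run and mean +/- SD offsets.}
#'   \item{motion_stability}{intrinsic (droop, bladder, GI) and extrinsic
#'     (cradle transfer) motion of the mouse phantom, difference-image
#'     summaries and rigid re-registration residuals.}
#'   \item{adrenal}{contrast-to-noise of the adrenals in CT vs MR,
#'     size-matched collimator choice and a single anterior-posterior
#'     beam; adrenal and kidney dose statistics.}
#'   \item{kpc_dvh}{the four comparative plans on the KPC-style phantom;
#'     four DVH CSVs plus an ordinal comparison summary.}
#' }
#'
#' @param config named list or path to a YAML file.  Common fields:
#'   `experiment`, `seed`, `output_dir`; per-experiment parameter blocks
#'   are passed through to the underlying functions.
#' @param outDir output directory (overrides `config$output_dir`).
#' @param dryRun validate the configuration and return the resolved
#'   parameters without computing.
#' @return the manifest (invisibly), also written to
#'   `<outDir>/manifest.json`.
#' @export
runExperiment <- function(config, outDir = NULL, dryRun = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  exp <- config$experiment
  if (is.null(exp) || !exp %in% c("gel_targeting", "motion_stability",
                                  "adrenal", "kpc_dvh"))
    stop("config$experiment must be one of gel_targeting, motion_stability, ",
         "adrenal, kpc_dvh")
  if (is.null(outDir)) outDir <- config$output_dir
  if (is.null(outDir)) stop("an output directory is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- config$params
  if (is.null(params)) params <- list()
  resolved <- list(experiment = exp, seed = seed, params = params,
                   output_dir = outDir)
  if (dryRun) return(invisible(resolved))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(exp,
    gel_targeting = .expGelTargeting(seed, params, outDir),
    motion_stability = .expMotionStability(seed, params, outDir),
    adrenal = .expAdrenal(seed, params, outDir),
    kpc_dvh = .expKpcDvh(seed, params, outDir))
  manifest <- c(list(package = "murt",
                     version = as.character(utils::packageVersion("murt")),
                     experiment = exp, seed = seed, parameters = params),
                res)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  missing <- res$artifacts[!file.exists(file.path(outDir, unlist(res$artifacts)))]
  if (length(missing))
    stop("experiment stage failed: missing artifacts ",
         paste(unlist(missing), collapse = ", "))
  invisible(manifest)
}

.p <- function(params, name, default) {
  v <- params[[name]]
  if (is.null(v)) default else v
}

.expGelTargeting <- function(seed, params, outDir) {
  spec <- gelPhantomSpec(ctSpacingMm = .p(params, "ct_spacing_mm", 0.16),
                         mrSpacingMm = .p(params, "mr_spacing_mm", 0.27),
                         mrSNR = .p(params, "mr_snr", 20))
  rep <- gelTargetingExperiment(
    runs = .p(params, "runs", 5), seed = seed, spec = spec,
    jitterSigmaMm = .p(params, "jitter_sigma_mm", 0.25),
    controlPoints = .p(params, "control_points", 36))
  out <- list(perRun = rep@runs, meanOffsetMm = rep@meanOffsetMm,
              sdOffsetMm = rep@sdOffsetMm, voxelSizeMm = rep@voxelSizeMm)
  jsonlite::write_json(out, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  list(metrics = list(mean_offset_mm = rep@meanOffsetMm,
                      sd_offset_mm = rep@sdOffsetMm),
       artifacts = list("report.json"))
}

.expMotionStability <- function(seed, params, outDir) {
  spec <- mousePhantomSpec(ctSpacingMm = .p(params, "ct_spacing_mm", 0.4),
                           mrSpacingMm = .p(params, "mr_spacing_mm", 0.4),
                           seed = seed)
  ph <- makeMousePhantom(spec, noise = FALSE)
  mo <- motionSpec(droopAmplitudeMm = .p(params, "droop_mm", 1),
                   bladderGrowthFraction = .p(params, "bladder_growth", 0.15),
                   giAmplitudeMm = .p(params, "gi_mm", 0.5), seed = seed)
  intr <- applyMotion(ph$bssfpClean, mo, "intrinsic", truth = ph$truthMR)
  diffI <- differenceImage(intr$result, ph$bssfpClean,
                           structures = ph$truthMR)
  writeVolume(diffI, file.path(outDir, "intrinsic_difference.nii.gz"))
  ex <- motionSpec(jitterRotationDeg = .p(params, "jitter_rot_deg", 2),
                   jitterTranslationMm = .p(params, "jitter_trans_mm", 0.5),
                   seed = seed + 1)
  extr <- applyMotion(ph$bssfpClean, ex, "extrinsic")
  resid <- NA_real_
  if (ex@jitterRotationDeg > 0 || ex@jitterTranslationMm > 0) {
    rec <- rigidRegisterIntensity(extr$result, ph$bssfpClean, metric = "MI")
    err <- composeRigid(rec, extr$transform)
    resid <- sqrt(sum(err@translation^2))
  }
  regions <- attr(diffI, "regions")
  write.csv(regions, file.path(outDir, "intrinsic_regions.csv"),
            row.names = FALSE)
  list(metrics = list(
         max_intrinsic_displacement_mm = max(abs(intr$field@displacements)),
         mean_abs_difference = mean(abs(diffI@voxels)),
         extrinsic_residual_translation_mm = resid),
       artifacts = list("intrinsic_difference.nii.gz",
                        "intrinsic_regions.csv"))
}

.expAdrenal <- function(seed, params, outDir) {
  spec <- mousePhantomSpec(ctSpacingMm = .p(params, "ct_spacing_mm", 0.4),
                           mrSpacingMm = .p(params, "mr_spacing_mm", 0.4),
                           seed = seed)
  ph <- makeMousePhantom(spec)
  sigmaMR <- spec@contrast$MR_bSSFP[["body"]] / spec@mrSNR
  cnrCT <- contrastToNoise(ph$ct, ph$truth, "adrenal_L", spec@ctNoiseSigma)
  cnrMR <- contrastToNoise(ph$bssfp, ph$truthMR, "adrenal_L", sigmaMR)
  coll <- chooseCollimator(ph$truthMR, name = "adrenal_L")
  iso <- defineIsocentre(ph$truth, name = "adrenal_L")
  beam <- beamSpec("static", isocentreMm = iso, collimatorMm = coll,
                   gantryDeg = 0)
  plan <- treatmentPlan(list(beam), .p(params, "dose_gy", 10))
  dose <- planDose(ph$ctClean, plan)
  writeVolume(dose, file.path(outDir, "adrenal_dose.nii.gz"))
  list(metrics = list(
         adrenal_cnr_ct = cnrCT, adrenal_cnr_bssfp = cnrMR,
         collimator_mm = coll,
         target_adrenal_mean_gy = meanDose(dose, ph$truth, "adrenal_L"),
         spared_adrenal_mean_gy = meanDose(dose, ph$truth, "adrenal_R"),
         adjacent_kidney_mean_gy = meanDose(dose, ph$truth, "kidney_L")),
       artifacts = list("adrenal_dose.nii.gz"))
}

.expKpcDvh <- function(seed, params, outDir) {
  cmp <- kpcPlanComparison(
    spec = mousePhantomSpec(ctSpacingMm = .p(params, "ct_spacing_mm", 0.3),
                            mrSpacingMm = .p(params, "mr_spacing_mm", 0.3),
                            seed = seed),
    doseSpacingMm = .p(params, "dose_spacing_mm", 0.4),
    prescriptionGy = .p(params, "prescription_gy", 8),
    collimatorMm = .p(params, "collimator_mm", 10),
    controlPoints = .p(params, "control_points", 36))
  arts <- list()
  for (nm in names(cmp$dvh)) {
    f <- paste0("dvh_", nm, ".csv")
    writeDVH(cmp$dvh[[nm]], file.path(outDir, f))
    arts <- c(arts, f)
  }
  write.csv(cmp$metrics, file.path(outDir, "plan_metrics.csv"),
            row.names = FALSE)
  arts <- c(arts, "plan_metrics.csv")
  m <- cmp$metrics
  ord <- list(
    tumour_d95_spread_frac = diff(range(m$tumourD95Gy)) / max(m$tumourD95Gy),
    ipsilateral_kidney_highest_plan = m$plan[which.max(m$kidneyRMeanGy)],
    contralateral_kidney_lowest_plan = m$plan[which.min(m$kidneyLMeanGy)],
    stomach_bowel_low_dose_larger_for_2x120 =
      m$stomachBowelLowDoseFrac[m$plan == "gantry2x120"] >
        m$stomachBowelLowDoseFrac[m$plan == "beam0"])
  list(metrics = ord, artifacts = arts)
}
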