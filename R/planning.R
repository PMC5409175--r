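#' Define an isocentre from a target mask or weighted image
#'
#' The mask (or intensity-weighted) centroid in world mm, optionally
#' perturbed by a zero-mean Gaussian operator-jitter model emulating a
#' trained operator prescribing the centre manually (the radial offset of
#' a 3D Gaussian has mean `2 sigma sqrt(2/pi)`).
#'
#' @param target logical array (with `gridObj` supplying the affine), a
#'   [StructureSet-class] (use `name`), or an [ImageVolume-class] whose
#'   voxel values act as weights.
#' @param gridObj object carrying the affine when `target` is an array.
#' @param name structure name when `target` is a StructureSet.
#' @param jitterSigmaMm operator jitter sd per axis, mm (0 disables).
#' @param seed seed for the jitter draw.
#' @return world-mm point (length-3).
#' @export
defineIsocentre <- function(target, gridObj = NULL, name = NULL,
                            jitterSigmaMm = 0, seed = NULL) {
  if (is(target, "StructureSet")) {
    nm <- if (is.null(name)) structureNames(target)[1] else name
    ctr <- maskCentroid(structureMask(target, nm), target)
  } else if (is(target, "ImageVolume")) {
    w <- target@voxels
    if (sum(w) <= 0) stop("empty target: no positive weights")
    idx <- which(w > 0, arr.ind = TRUE)
    ctr <- colSums(voxelToWorld(target, idx) * w[idx]) / sum(w[idx])
  } else {
    if (!any(target)) stop("empty target mask")
    ctr <- maskCentroid(target, gridObj)
  }
  if (jitterSigmaMm > 0)
    ctr <- ctr + withSeed(seed, rnorm(3, 0, jitterSigmaMm))
  as.numeric(ctr)
}

#' Choose the collimator matched to a target's size
#'
#' The smallest available diameter covering the target's maximal
#' beam's-eye-view extent (the diameter of the target silhouette in the
#' plane perpendicular to the beam), matching the practice of sizing the
#' field to the imaged target.
#'
#' @param target StructureSet (+ `name`) or logical array (+ `gridObj`).
#' @param available available collimator diameters, mm.
#' @param beamDirection unit beam direction (default vertical).
#' @param gridObj,name as in [defineIsocentre()].
#' @return chosen diameter (mm); if no collimator covers the target a
#'   coverage warning suggests composing multiple fields and the largest
#'   available diameter is returned.
#' @export
chooseCollimator <- function(target, available = c(2, 3, 5, 10),
                             beamDirection = c(0, -1, 0), gridObj = NULL,
                             name = NULL) {
  if (is(target, "StructureSet")) {
    nm <- if (is.null(name)) structureNames(target)[1] else name
    m <- structureMask(target, nm)
    gridObj <- target
  } else m <- target
  if (!any(m)) stop("empty target mask")
  d <- dim(m)
  b <- array(boundary_mask_cpp(as.logical(m), as.integer(d)), d)
  pts <- voxelToWorld(gridObj, which(b, arr.ind = TRUE))
  e <- beamDirection / sqrt(sum(beamDirection^2))
  # silhouette diameter: maximal pairwise distance of the projections
  proj <- pts - outer(as.numeric(pts %*% e), e)
  if (nrow(proj) > 600) proj <- proj[round(seq(1, nrow(proj), length.out = 600)), ]
  extent <- max(stats::dist(proj))
  avail <- sort(available)
  ok <- avail[avail >= extent]
  if (!length(ok)) {
    warning(sprintf(paste("no available collimator covers the %.1f mm",
                          "target extent: compose more than one field",
                          "with minimal overlap"), extent))
    return(max(avail))
  }
  ok[1]
}

#' The four comparative plan geometries
#'
#' (1) a single conical arc with the gantry at 45 degrees and a full
#' subject rotation; (2) a single static vertical beam; (3) two conical
#' arcs with the gantry at 30 and 60 degrees; (4) two gantry arcs sweeping
#' 0 to +120 and 0 to -120 degrees (240 degrees of source travel,
#' equivalent to moving the gantry from -120 to +120 degrees).
#'
#' @param isocentreMm world-mm isocentre.
#' @param collimatorMm collimator diameter, mm (10 for the abdominal
#'   plan comparison).
#' @param prescriptionGy prescription, Gy.
#' @param sadMm source-axis distance.
#' @return named list of [Plan-class] objects: `arc45`, `beam0`,
#'   `arc3060`, `gantry2x120`.
#' @export
makeComparisonPlans <- function(isocentreMm, collimatorMm = 10,
                                prescriptionGy = 8, sadMm = 350) {
  mk <- function(...) beamSpec(..., isocentreMm = isocentreMm,
                               collimatorMm = collimatorMm, sadMm = sadMm)
  list(
    arc45 = treatmentPlan(list(mk("conical_arc", gantryDeg = 45)),
                          prescriptionGy),
    beam0 = treatmentPlan(list(mk("static", gantryDeg = 0)), prescriptionGy),
    arc3060 = treatmentPlan(list(mk("conical_arc", gantryDeg = 30),
                                 mk("conical_arc", gantryDeg = 60)),
                            prescriptionGy),
    gantry2x120 = treatmentPlan(list(mk("gantry_arc", sweepDeg = c(0, 120)),
                                     mk("gantry_arc", sweepDeg = c(0, -120))),
                                prescriptionGy))
}

#' Cumulative dose-volume histograms
#'
#' Percent of each structure's volume receiving at least each dose level:
#' 100% at 0 Gy, monotone non-increasing, 0% above the maximum dose.
#'
#' @param dose a [DoseGrid-class].
#' @param structures a [StructureSet-class] on the same grid.
#' @param binWidthGy dose bin width (default 0.1 Gy).
#' @return a [DVHCurve-class].
#' @export
computeDVH <- function(dose, structures, binWidthGy = 0.1) {
  if (!all(dim(dose@voxels) == dim(structures@labels)) ||
      max(abs(dose@affine - structures@affine)) > 1e-6)
    stop("dose and structures must share a grid")
  maxD <- max(dose@voxels)
  edges <- seq(0, maxD + binWidthGy, by = binWidthGy)
  nms <- structureNames(structures)
  curves <- matrix(0, length(nms), length(edges),
                   dimnames = list(nms, NULL))
  for (nm in nms) {
    v <- dose@voxels[structureMask(structures, nm)]
    if (!length(v)) next
    curves[nm, ] <- 100 * (1 - stats::ecdf(v)(edges - 1e-12))
    curves[nm, 1] <- 100
  }
  new("DVHCurve", doseGy = edges, volumePct = curves)
}

#' Dose metrics from raw voxel doses
#'
#' `Dxx` is the dose received by at least xx% of the structure (e.g. D95);
#' `Dmean` the mean dose; `Vlo_hi` the fraction of volume receiving a dose
#' in (lo, hi].
#'
#' @param dose a [DoseGrid-class].
#' @param structures StructureSet on the same grid.
#' @param name structure name.
#' @export
doseQuantile <- function(dose, structures, name, coverage = 95) {
  v <- dose@voxels[structureMask(structures, name)]
  as.numeric(quantile(v, 1 - coverage / 100, type = 7))
}

#' @rdname doseQuantile
#' @export
meanDose <- function(dose, structures, name)
  mean(dose@voxels[structureMask(structures, name)])

#' @rdname doseQuantile
#' @param loGy,hiGy dose range bounds, Gy.
#' @param coverage coverage percentage for `doseQuantile`.
#' @export
volumeFractionInRange <- function(dose, structures, name, loGy, hiGy) {
  v <- dose@voxels[structureMask(structures, name)]
  mean(v > loGy & v <= hiGy)
}

#' DVH value lookup
#'
#' Evaluates the cumulative curve at a dose level.  At a bin edge the
#' stored value is returned; between edges the next edge's value is used
#' (the curve can only have stepped down inside the bin).
#'
#' @param dvh a [DVHCurve-class].
#' @param name structure.
#' @param doseGy dose level.
#' @return cumulative volume percent at `doseGy`.
#' @export
dvhAt <- function(dvh, name, doseGy) {
  vapply(doseGy, function(d) {
    i <- which(dvh@doseGy >= d - 1e-9)[1]
    if (is.na(i)) 0 else unname(dvh@volumePct[name, i])
  }, 1)
}

#' Write DVH curves as CSV (structure, bin_gy, cum_vol_pct)
#' @param dvh a [DVHCurve-class].
#' @param path output path.
#' @export
writeDVH <- function(dvh, path) {
  df <- do.call(rbind, lapply(rownames(dvh@volumePct), function(nm)
    data.frame(structure = nm, bin_gy = dvh@doseGy,
               cum_vol_pct = dvh@volumePct[nm, ])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
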