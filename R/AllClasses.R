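#' ImageVolume: a 3D scalar grid in world millimetres
#'
#' The common currency of the toolkit: a 3D array of voxel values plus a
#' 4x4 affine mapping 0-based voxel indices (i,j,k,1) to world mm, a
#' modality tag and a world-frame tag.
#'
#' @slot voxels 3D numeric array (HU-like for CT, signal for MR, Gy for dose).
#' @slot affine 4x4 voxel-index (0-based) to world-mm matrix.
#' @slot modality one of `"CT"`, `"MR_bSSFP"`, `"MR_CPMG"`, `"MR_CEFAST"`,
#'   `"DOSE"`, `"LABEL"`.
#' @slot frame world-frame tag (volumes sharing a frame may be compared
#'   voxel-to-voxel once on a common grid).
#' @export
setClass("ImageVolume",
  representation(voxels = "array", affine = "matrix",
                 modality = "character", frame = "character"),
  prototype(modality = "CT", frame = "world"))

.validModalities <- c("CT", "MR_bSSFP", "MR_CPMG", "MR_CEFAST", "DOSE", "LABEL")

setValidity("ImageVolume", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L)
    msgs <- c(msgs, "voxels must be a 3D array")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msgs <- c(msgs, "affine must be 4x4")
  else {
    d <- det(object@affine)
    if (!is.finite(d) || abs(d) < 1e-12)
      msgs <- c(msgs, "affine must be invertible")
    sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
    if (any(sp <= 0))
      msgs <- c(msgs, "voxel spacings must be strictly positive")
  }
  if (!object@modality %in% .validModalities)
    msgs <- c(msgs, paste("modality must be one of:",
                          paste(.validModalities, collapse = ", ")))
  if (object@modality == "DOSE" && any(object@voxels < -1e-9, na.rm = TRUE))
    msgs <- c(msgs, "DOSE volumes must be non-negative everywhere")
  if (length(msgs)) msgs else TRUE
})

#' DoseGrid: an ImageVolume holding absorbed dose in Gy
#'
#' @export
setClass("DoseGrid", contains = "ImageVolume",
         prototype = prototype(modality = "DOSE"))

setValidity("DoseGrid", function(object) {
  if (object@modality != "DOSE") return("DoseGrid modality must be 'DOSE'")
  TRUE
})

#' RigidTransform: a rigid world-space map (rotation + translation)
#'
#' Maps points as `rotation %*% p + translation`, both in world mm.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric, mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  msgs <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    msgs <- c(msgs, "rotation must be orthonormal (R'R = I within 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    msgs <- c(msgs, "rotation determinant must be +1 within 1e-9")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    msgs <- c(msgs, "translation must be a finite length-3 vector")
  if (length(msgs)) msgs else TRUE
})

#' DeformationField: dense per-voxel displacements on a stated grid
#'
#' `displacements[i,j,k,]` is the world-mm displacement added to the world
#' position of grid voxel (i,j,k) before sampling the moving image
#' (a backward/pull-back field, the convention used by [resample()]).
#'
#' @slot displacements 4D array (nx, ny, nz, 3), mm.
#' @slot affine 4x4 voxel-to-world affine of the field's grid.
#' @export
setClass("DeformationField",
  representation(displacements = "array", affine = "matrix"))

setValidity("DeformationField", function(object) {
  d <- dim(object@displacements)
  if (length(d) != 4L || d[4] != 3L)
    return("displacements must be a 4D array with last dimension 3")
  if (any(!is.finite(object@displacements)))
    return("displacements must be finite everywhere")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be 4x4")
  TRUE
})

#' StructureSet: named integer-label masks on a reference grid
#'
#' Label 0 is background; every nonzero label present must be named.
#'
#' @slot labels 3D integer array sharing an affine with a reference volume.
#' @slot affine 4x4 voxel-to-world affine.
#' @slot labelNames named integer vector, structure name -> label value.
#' @slot metadata list of free-form annotations (e.g. generator warnings).
#' @export
setClass("StructureSet",
  representation(labels = "array", affine = "matrix",
                 labelNames = "integer", metadata = "list"),
  prototype(metadata = list()))

setValidity("StructureSet", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3L)
    msgs <- c(msgs, "labels must be a 3D array")
  present <- setdiff(unique(as.integer(object@labels)), 0L)
  if (!all(present %in% object@labelNames))
    msgs <- c(msgs, "every nonzero label must have a name in labelNames")
  if (is.null(names(object@labelNames)) &&
      length(object@labelNames) > 0)
    msgs <- c(msgs, "labelNames must be named")
  if (length(msgs)) msgs else TRUE
})

#' PointCloud: N x 3 world-mm points (optionally with unit normals)
#'
#' @slot points numeric matrix, one point per row.
#' @slot normals unit surface normals per point (0-row matrix when absent).
#' @export
setClass("PointCloud",
         representation(points = "matrix", normals = "matrix"),
         prototype(normals = matrix(numeric(), 0, 3)))

setValidity("PointCloud", function(object) {
  if (ncol(object@points) != 3L) return("points must have 3 columns")
  if (any(!is.finite(object@points))) return("points must be finite")
  if (nrow(object@normals) && nrow(object@normals) != nrow(object@points))
    return("normals must match points row-for-row")
  TRUE
})

#' @rdname PointCloud-class
#' @param points,normals matrices (n x 3).
#' @export
pointCloud <- function(points, normals = matrix(numeric(), 0, 3))
  new("PointCloud", points = points, normals = normals)

#' MINDDescriptor: per-voxel modality-independent neighbourhood descriptors
#'
#' @slot descriptors matrix (nvox x stencil size), components in (0, 1].
#' @slot dim grid dimensions.
#' @slot affine grid affine.
#' @slot sigma patch Gaussian sigma in voxels.
#' @export
setClass("MINDDescriptor",
  representation(descriptors = "matrix", dim = "integer",
                 affine = "matrix", sigma = "numeric"))

#' BeamSpec: geometry of one collimated kV beam or arc
#'
#' @slot kind `"static"`, `"conical_arc"` or `"gantry_arc"`.
#' @slot gantryDeg gantry angle from vertical, degrees (static, conical_arc).
#' @slot sweepDeg length-2 start/end gantry angle, degrees (gantry_arc).
#' @slot subjectSweepDeg subject rotation sweep for conical arcs (360).
#' @slot collimatorMm circular collimator diameter at the isocentre plane, mm.
#' @slot sadMm source-axis distance, mm.
#' @slot isocentreMm world-mm isocentre.
#' @slot weight relative beam weight (> 0).
#' @slot direction optional explicit unit beam direction (overrides gantry).
#' @export
setClass("BeamSpec",
  representation(kind = "character", gantryDeg = "numeric",
                 sweepDeg = "numeric", subjectSweepDeg = "numeric",
                 collimatorMm = "numeric", sadMm = "numeric",
                 isocentreMm = "numeric", weight = "numeric",
                 direction = "numeric"),
  prototype(kind = "static", gantryDeg = 0, sweepDeg = numeric(),
            subjectSweepDeg = 360, collimatorMm = 5, sadMm = 350,
            weight = 1, direction = numeric()))

setValidity("BeamSpec", function(object) {
  msgs <- character()
  if (!object@kind %in% c("static", "conical_arc", "gantry_arc"))
    msgs <- c(msgs, "kind must be static, conical_arc or gantry_arc")
  if (object@collimatorMm <= 0) msgs <- c(msgs, "collimator must be > 0")
  if (object@sadMm <= 0) msgs <- c(msgs, "SAD must be > 0")
  if (object@weight < 0) msgs <- c(msgs, "weight must be >= 0")
  if (length(object@isocentreMm) != 3L)
    msgs <- c(msgs, "isocentre must be a length-3 world point")
  if (object@kind == "gantry_arc" && length(object@sweepDeg) != 2L)
    msgs <- c(msgs, "gantry_arc needs sweepDeg = c(start, end)")
  if (length(msgs)) msgs else TRUE
})

#' Plan: a weighted set of beams with a prescription
#'
#' @slot beams list of [BeamSpec-class] objects.
#' @slot prescriptionGy prescription dose, Gy (> 0).
#' @slot normalization `"isocentre"` or `"target_mean"`.
#' @export
setClass("Plan",
  representation(beams = "list", prescriptionGy = "numeric",
                 normalization = "character"),
  prototype(normalization = "isocentre"))

setValidity("Plan", function(object) {
  msgs <- character()
  if (!length(object@beams)) msgs <- c(msgs, "plan needs at least one beam")
  if (!all(vapply(object@beams, is, TRUE, "BeamSpec")))
    msgs <- c(msgs, "beams must be BeamSpec objects")
  if (object@prescriptionGy <= 0) msgs <- c(msgs, "prescription must be > 0")
  if (!object@normalization %in% c("isocentre", "target_mean"))
    msgs <- c(msgs, "normalization must be isocentre or target_mean")
  if (length(msgs)) msgs else TRUE
})

#' DVHCurve: cumulative dose-volume histograms per structure
#'
#' @slot doseGy dose bin edges, Gy (starting at 0).
#' @slot volumePct matrix (structure x bin edge) of cumulative volume
#'   percentages: percent of the structure receiving at least that dose.
#' @export
setClass("DVHCurve",
  representation(doseGy = "numeric", volumePct = "matrix"))

setValidity("DVHCurve", function(object) {
  v <- object@volumePct
  if (ncol(v) != length(object@doseGy))
    return("volumePct columns must match doseGy")
  if (any(v < -1e-9 | v > 100 + 1e-9)) return("volumes must be in [0, 100]%")
  if (any(apply(v, 1, function(r) any(diff(r) > 1e-9))))
    return("cumulative DVH must be non-increasing")
  TRUE
})

#' TargetingReport: end-to-end targeting accuracy of the MR-IGRT chain
#'
#' @slot runs data.frame with one row per run: seed, the segmented
#'   cross-beam target centre and delivered dose-region centre (mm), the 3D
#'   offset in mm and in voxels.
#' @slot meanOffsetMm mean 3D offset across runs, mm.
#' @slot sdOffsetMm standard deviation of the offset across runs, mm.
#' @slot voxelSizeMm voxel size used for the pixel-unit conversion, mm.
#' @export
setClass("TargetingReport",
  representation(runs = "data.frame", meanOffsetMm = "numeric",
                 sdOffsetMm = "numeric", voxelSizeMm = "numeric"))

setValidity("TargetingReport", function(object) {
  if (any(object@runs$offsetMm < 0)) return("offsets must be >= 0")
  TRUE
})
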