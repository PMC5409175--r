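#' Accessors for image-like objects
#'
#' `voxels()` returns the raw 3D array, `imageAffine()` the 4x4
#' voxel-to-world matrix, `modality()` the modality tag and
#' `voxelSpacing()` the per-axis spacings in mm.
#'
#' @param x an [ImageVolume-class], [StructureSet-class] or
#'   [DeformationField-class] as applicable.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("imageAffine", function(x) standardGeneric("imageAffine"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Resample an image onto a target grid through a spatial transform
#'
#' @param moving the image to resample.
#' @param transform a [RigidTransform-class] mapping moving-world to
#'   target-world, a [DeformationField-class] on the target grid, `NULL`
#'   (identity), or a list with elements `rigid` and/or `field` applied as a
#'   chain.
#' @param target an [ImageVolume-class] (or [StructureSet-class]) whose grid
#'   defines the output.
#' @param ... further arguments: `interpolation` (`"linear"` or
#'   `"nearest"`; LABEL volumes default to nearest) and `fill` (out-of-field
#'   value, default 0).
#' @export
setGeneric("resample", function(moving, transform, target, ...)
  standardGeneric("resample"))

#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' Extract one structure's logical mask
#' @param x a [StructureSet-class].
#' @param name structure name.
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))
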