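#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array.
#' @param affine 4x4 voxel-to-world (mm) matrix mapping 0-based indices; or
#'   `NULL` to build an axis-aligned affine from `spacing` and `origin`.
#' @param modality modality tag (see [ImageVolume-class]).
#' @param spacing,origin used when `affine` is `NULL`.
#' @param frame world frame tag.
#' @return an [ImageVolume-class] (a [DoseGrid-class] when `modality` is
#'   `"DOSE"`).
#' @export
imageVolume <- function(voxels, affine = NULL, modality = "CT",
                        spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        frame = "world") {
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- origin
  }
  storage.mode(voxels) <- "double"
  cls <- if (modality == "DOSE") "DoseGrid" else "ImageVolume"
  new(cls, voxels = voxels, affine = affine, modality = modality,
      frame = frame)
}

#' @describeIn imageVolume coerce a dose array onto an existing grid.
#' @param reference an ImageVolume supplying the grid.
#' @export
asDoseGrid <- function(voxels, reference) {
  voxels[voxels < 0 & voxels > -1e-9] <- 0
  imageVolume(voxels, affine = imageAffine(reference), modality = "DOSE",
              frame = reference@frame)
}

#' @rdname accessors
#' @export
setMethod("voxels", "ImageVolume", function(x) x@voxels)

#' @export
setMethod("imageAffine", "ImageVolume", function(x) x@affine)

#' @export
setMethod("imageAffine", "StructureSet", function(x) x@affine)

#' @export
setMethod("imageAffine", "DeformationField", function(x) x@affine)

#' @export
setMethod("modality", "ImageVolume", function(x) x@modality)

#' @export
setMethod("voxelSpacing", "ImageVolume",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @export
setMethod("voxelSpacing", "StructureSet",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  sp <- voxelSpacing(object)
  cat(sprintf("%s <%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(object), object@modality, d[1], d[2], d[3],
              sp[1], sp[2], sp[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, frame '%s', range [%.3g, %.3g]\n",
              object@affine[1, 4], object@affine[2, 4], object@affine[3, 4],
              object@frame, min(object@voxels), max(object@voxels)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngleDeg(object)
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "StructureSet", function(object) {
  d <- dim(object@labels)
  cat(sprintf("StructureSet %d x %d x %d with %d structures: %s\n",
              d[1], d[2], d[3], length(object@labelNames),
              paste(names(object@labelNames), collapse = ", ")))
})

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve: %d structures, %d dose bins (0 to %.2f Gy)\n",
              nrow(object@volumePct), length(object@doseGy),
              max(object@doseGy)))
})

setMethod("show", "TargetingReport", function(object) {
  cat(sprintf("TargetingReport: %d runs, mean offset %.3f +/- %.3f mm (%.2f +/- %.2f voxels at %.3g mm)\n",
              nrow(object@runs), object@meanOffsetMm, object@sdOffsetMm,
              object@meanOffsetMm / object@voxelSizeMm,
              object@sdOffsetMm / object@voxelSizeMm, object@voxelSizeMm))
})

## ---- coordinates -----------------------------------------------------------

#' Voxel/world coordinate conversion
#'
#' Indices are 1-based on the R side; the affine maps 0-based indices, so
#' the conversion subtracts 1.
#'
#' @param x an object with an affine (ImageVolume, StructureSet, ...).
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxelToWorld <- function(x, ijk) {
  A <- imageAffine(x)
  ijk <- rbind(ijk)
  h <- cbind(ijk - 1, 1) %*% t(A)
  h[, 1:3, drop = FALSE]
}

#' @rdname voxelToWorld
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return for `worldToVoxel`, n x 3 matrix of continuous 1-based indices.
#' @export
worldToVoxel <- function(x, xyz) {
  A <- imageAffine(x)
  xyz <- rbind(xyz)
  h <- cbind(xyz, 1) %*% t(solve(A))
  h[, 1:3, drop = FALSE] + 1
}

#' World coordinate arrays of every voxel centre
#'
#' Returns a list of three arrays (x, y, z), each with the grid's dim,
#' holding the world-mm coordinate of each voxel centre.  Exploits
#' axis-aligned affines where possible.
#' @param x object with an affine and a grid.
#' @export
worldGrid <- function(x) {
  A <- imageAffine(x)
  d <- gridDim(x)
  i <- seq_len(d[1]) - 1; j <- seq_len(d[2]) - 1; k <- seq_len(d[3]) - 1
  off <- A[1:3, 4]
  L <- A[1:3, 1:3]
  xs <- outer(L[1, 1] * i, L[1, 2] * j, "+")
  ys <- outer(L[2, 1] * i, L[2, 2] * j, "+")
  zs <- outer(L[3, 1] * i, L[3, 2] * j, "+")
  gx <- outer(c(xs), L[1, 3] * k, "+") + off[1]
  gy <- outer(c(ys), L[2, 3] * k, "+") + off[2]
  gz <- outer(c(zs), L[3, 3] * k, "+") + off[3]
  dim(gx) <- d; dim(gy) <- d; dim(gz) <- d
  list(x = gx, y = gy, z = gz)
}

gridDim <- function(x) {
  if (is(x, "ImageVolume")) dim(x@voxels)
  else if (is(x, "StructureSet")) dim(x@labels)
  else if (is(x, "DeformationField")) dim(x@displacements)[1:3]
  else stop("no grid for class ", class(x))
}

## ---- rigid transforms ------------------------------------------------------

#' Construct a rigid transform
#'
#' @param rotation 3x3 rotation matrix, or `NULL` to build from Euler
#'   angles `anglesDeg` (applied as Rz Ry Rx, degrees).
#' @param translation length-3 translation, mm.
#' @param anglesDeg length-3 Euler angles (about x, y, z), degrees.
#' @param centre optional rotation centre (mm): the map becomes
#'   `R (p - c) + c + t`.
#' @export
rigidTransform <- function(rotation = NULL, translation = c(0, 0, 0),
                           anglesDeg = c(0, 0, 0), centre = NULL) {
  if (is.null(rotation)) rotation <- eulerRotation(anglesDeg)
  if (!is.null(centre))
    translation <- translation + as.numeric(centre - rotation %*% centre)
  new("RigidTransform", rotation = rotation, translation = translation)
}

eulerRotation <- function(anglesDeg) {
  a <- anglesDeg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Rotation magnitude of a rigid transform, degrees
#' @param t a [RigidTransform-class].
#' @export
rotationAngleDeg <- function(t) {
  ct <- (sum(diag(t@rotation)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Compose two rigid transforms: apply `b` first, then `a`
#' @param a,b rigid transforms.
#' @export
composeRigid <- function(a, b) {
  R <- a@rotation %*% b@rotation
  # re-orthonormalize to keep composition closed under the validity invariant
  s <- svd(R)
  R <- s$u %*% t(s$v)
  new("RigidTransform", rotation = R,
      translation = as.numeric(a@rotation %*% b@translation + a@translation))
}

#' Invert a rigid transform
#' @param t a [RigidTransform-class].
#' @export
invertRigid <- function(t) {
  Rt <- t(t@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.numeric(-Rt %*% t@translation))
}

#' Apply a rigid transform to points
#' @param t a [RigidTransform-class].
#' @param pts n x 3 matrix (or length-3 vector) of world mm points.
#' @export
applyRigid <- function(t, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(t@rotation), 2, t@translation, "+")
}

rigidToMatrix <- function(t) {
  M <- diag(4)
  M[1:3, 1:3] <- t@rotation
  M[1:3, 4] <- t@translation
  M
}

## ---- resampling ------------------------------------------------------------

.interpCode <- function(interpolation, modality) {
  if (is.null(interpolation))
    interpolation <- if (modality == "LABEL") "nearest" else "linear"
  match.arg(interpolation, c("linear", "nearest"))
}

.resampleArray <- function(arr, movAffine, transform, target, interpolation,
                           fill) {
  odim <- gridDim(target)
  Atgt <- imageAffine(target)
  mdim <- dim(arr)
  storage.mode(arr) <- "double"
  interp <- if (interpolation == "linear") 0L else 1L
  if (is.null(transform) || is(transform, "RigidTransform")) {
    Tinv <- if (is.null(transform)) diag(4) else rigidToMatrix(invertRigid(transform))
    C <- solve(movAffine) %*% Tinv %*% Atgt
    out <- resample_affine_cpp(arr, as.integer(mdim), as.integer(odim), C,
                               interp, fill)
  } else if (is(transform, "DeformationField")) {
    fd <- dim(transform@displacements)[1:3]
    if (!all(fd == odim) ||
        max(abs(transform@affine - Atgt)) > 1e-6)
      stop("DeformationField grid is incompatible with the target grid")
    u <- transform@displacements
    out <- resample_field_cpp(arr, as.integer(mdim), as.integer(odim), Atgt,
                              solve(movAffine), as.numeric(u[, , , 1]),
                              as.numeric(u[, , , 2]), as.numeric(u[, , , 3]),
                              interp, fill)
  } else if (is.list(transform)) {
    # chain: world point x -> x + field(x) -> rigid^{-1} applied via
    # composition of the two pull-backs
    if (!is.null(transform$field)) {
      fl <- transform$field
      fd <- dim(fl@displacements)[1:3]
      if (!all(fd == odim) || max(abs(fl@affine - Atgt)) > 1e-6)
        stop("DeformationField grid is incompatible with the target grid")
      Tinv <- if (is.null(transform$rigid)) diag(4) else
        rigidToMatrix(invertRigid(transform$rigid))
      Binv <- solve(movAffine) %*% Tinv
      u <- fl@displacements
      out <- resample_field_cpp(arr, as.integer(mdim), as.integer(odim), Atgt,
                                Binv, as.numeric(u[, , , 1]),
                                as.numeric(u[, , , 2]), as.numeric(u[, , , 3]),
                                interp, fill)
    } else {
      return(.resampleArray(arr, movAffine, transform$rigid, target,
                            interpolation, fill))
    }
  } else stop("unsupported transform of class ", class(transform)[1])
  array(out, dim = odim)
}

#' @rdname resample
#' @param interpolation `"linear"` or `"nearest"`; `NULL` picks nearest for
#'   LABEL volumes and linear otherwise.
#' @param fill out-of-field fill value (default 0, air/background).
#' @export
setMethod("resample", signature("ImageVolume"),
  function(moving, transform, target, interpolation = NULL, fill = 0) {
    interpolation <- .interpCode(interpolation, moving@modality)
    v <- .resampleArray(moving@voxels, moving@affine, transform, target,
                        interpolation, fill)
    if (moving@modality == "DOSE") v[v < 0] <- 0
    out <- imageVolume(v, affine = imageAffine(target),
                       modality = moving@modality, frame = frameOf(target))
    out
  })

#' @rdname resample
#' @export
setMethod("resample", signature("StructureSet"),
  function(moving, transform, target, interpolation = "nearest", fill = 0) {
    arr <- moving@labels
    storage.mode(arr) <- "double"
    v <- .resampleArray(arr, moving@affine, transform, target, "nearest", fill)
    storage.mode(v) <- "integer"
    new("StructureSet", labels = v, affine = imageAffine(target),
        labelNames = moving@labelNames, metadata = moving@metadata)
  })

frameOf <- function(x) if (is(x, "ImageVolume")) x@frame else "world"

#' Downsample a volume by an integer factor (Gaussian anti-aliasing)
#' @param vol an ImageVolume.
#' @param factor integer factor >= 1.
#' @export
downsampleVolume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  d <- dim(vol@voxels)
  sm <- gauss_smooth3_cpp(as.numeric(vol@voxels), as.integer(d),
                          rep(factor / 2.5, 3))
  sm <- array(sm, d)
  idx <- lapply(d, function(n) seq(1, n, by = factor))
  sub <- sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  A <- vol@affine
  A2 <- A
  A2[1:3, 1:3] <- A[1:3, 1:3] * factor
  imageVolume(sub, affine = A2, modality = vol@modality, frame = vol@frame)
}

## ---- difference images -----------------------------------------------------

#' Voxelwise difference image (a - b)
#'
#' Both volumes must share grid and modality.  With a [StructureSet-class]
#' given, also computes per-region mean absolute difference expressed as a
#' percentage of the first image's regional mean (retrieve it with
#' [regionalDifference()] or the `"regions"` attribute).
#'
#' @param a,b ImageVolumes on a common grid.
#' @param structures optional StructureSet on the same grid.
#' @return signed difference as an ImageVolume; when `structures` is given
#'   the per-region summary data.frame is attached as attribute `regions`.
#' @export
differenceImage <- function(a, b, structures = NULL) {
  if (!all(dim(a@voxels) == dim(b@voxels)) ||
      max(abs(a@affine - b@affine)) > 1e-6)
    stop("difference image requires a common grid")
  if (a@modality != b@modality)
    stop("difference image requires a common modality")
  d <- imageVolume(a@voxels - b@voxels, affine = a@affine,
                   modality = a@modality, frame = a@frame)
  if (!is.null(structures))
    attr(d, "regions") <- regionalDifference(a, b, structures)
  d
}

#' @rdname differenceImage
#' @export
regionalDifference <- function(a, b, structures) {
  if (!all(dim(a@voxels) == dim(structures@labels)))
    stop("structures must share the image grid")
  diffs <- a@voxels - b@voxels
  res <- lapply(names(structures@labelNames), function(nm) {
    m <- structures@labels == structures@labelNames[[nm]]
    if (!any(m)) return(NULL)
    ma <- mean(abs(diffs[m]))
    ref <- mean(a@voxels[m])
    data.frame(structure = nm, meanAbsDiff = ma,
               pctOfFirst = 100 * ma / max(abs(ref), .Machine$double.eps))
  })
  do.call(rbind, res)
}

## ---- structure sets --------------------------------------------------------

#' Construct a StructureSet
#' @param labels integer 3D array (0 = background).
#' @param affine 4x4 voxel-to-world matrix.
#' @param labelNames named integer vector (name -> label).
#' @param metadata optional list.
#' @export
structureSet <- function(labels, affine, labelNames, metadata = list()) {
  storage.mode(labels) <- "integer"
  labelNames <- vapply(labelNames, as.integer, integer(1))
  new("StructureSet", labels = labels, affine = affine,
      labelNames = labelNames, metadata = metadata)
}

#' @export
setMethod("structureNames", "StructureSet",
          function(x) names(x@labelNames))

#' @export
setMethod("structureMask", "StructureSet", function(x, name) {
  if (!name %in% names(x@labelNames))
    stop("unknown structure '", name, "'")
  x@labels == x@labelNames[[name]]
})

#' Centroid (world mm) of a logical mask on a grid
#' @param mask logical 3D array.
#' @param gridObj object carrying the grid affine.
#' @export
maskCentroid <- function(mask, gridObj) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  colMeans(voxelToWorld(gridObj, idx))
}
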