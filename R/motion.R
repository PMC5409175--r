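#' Specification of intrinsic and extrinsic motion models
#'
#' Intrinsic motion combines a gravity-induced body droop (zero at the
#' cradle contact line, maximal at the surface farthest from it), bladder
#' filling (radial dilation about the bladder centre) and local
#' gastrointestinal-motility warps.  Extrinsic motion is a single rigid
#' pose perturbation, as introduced by transferring the animal cradle
#' between the MR scanner and the irradiator.  MR geometric distortion is
#' a smooth low-order polynomial warp.
#'
#' @slot droopAmplitudeMm peak droop displacement, mm (the reference scale
#'   exercises about 1 mm).
#' @slot bladderGrowthFraction fractional bladder radius growth.
#' @slot giAmplitudeMm peak gastrointestinal warp displacement, mm.
#' @slot jitterRotationDeg extrinsic pose rotation magnitude, degrees.
#' @slot jitterTranslationMm extrinsic pose translation magnitude, mm.
#' @slot distortionAmplitudeMm peak MR polynomial-warp displacement, mm.
#' @slot seed integer seed for the random draws.
#' @export
setClass("MotionSpec",
  representation(droopAmplitudeMm = "numeric",
                 bladderGrowthFraction = "numeric",
                 giAmplitudeMm = "numeric", jitterRotationDeg = "numeric",
                 jitterTranslationMm = "numeric",
                 distortionAmplitudeMm = "numeric", seed = "numeric"),
  prototype(droopAmplitudeMm = 0, bladderGrowthFraction = 0,
            giAmplitudeMm = 0, jitterRotationDeg = 0,
            jitterTranslationMm = 0, distortionAmplitudeMm = 0, seed = 1))

#' @rdname MotionSpec-class
#' @param ... slot overrides.
#' @export
motionSpec <- function(...) {
  s <- new("MotionSpec", ...)
  amps <- c(s@droopAmplitudeMm, s@bladderGrowthFraction, s@giAmplitudeMm,
            s@jitterRotationDeg, s@jitterTranslationMm,
            s@distortionAmplitudeMm)
  if (any(amps < 0)) stop("motion amplitudes must be >= 0")
  s
}

.gridOf <- function(x) {
  if (is(x, "ImageVolume")) x else
    imageVolume(array(0, dim(x@labels)), affine = x@affine,
                modality = "LABEL")
}

#' Apply a motion model to a volume or structure set
#'
#' Returns the moved object together with the exact ground-truth
#' displacement field (intrinsic, mr_distortion) or rigid transform
#' (extrinsic) that was applied, enabling oracle-based registration tests.
#' A zero spec returns the input bit-identically.
#'
#' @param x an [ImageVolume-class] or [StructureSet-class].
#' @param motion a [MotionSpec-class].
#' @param kind `"intrinsic"`, `"extrinsic"` or `"mr_distortion"`.
#' @param truth a [StructureSet-class] on `x`'s grid; required for bladder
#'   filling and GI warps (organ geometry) and used to locate the body for
#'   the droop profile.
#' @return list with `result` (same class as `x`) and `field`
#'   (a [DeformationField-class]) or `transform` (a
#'   [RigidTransform-class]).
#' @export
applyMotion <- function(x, motion, kind = c("intrinsic", "extrinsic",
                                            "mr_distortion"),
                        truth = NULL) {
  kind <- match.arg(kind)
  ref <- .gridOf(x)
  if (kind == "extrinsic") {
    if (motion@jitterRotationDeg == 0 && motion@jitterTranslationMm == 0)
      return(list(result = x, transform = rigidTransform()))
    tr <- withSeed(motion@seed, {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- motion@jitterRotationDeg * pi / 180
      K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
                 c(-ax[2], ax[1], 0))
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      tdir <- rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
      ctr <- as.numeric(voxelToWorld(ref, (gridDim(ref) + 1) / 2))
      rigidTransform(rotation = R,
                     translation = tdir * motion@jitterTranslationMm,
                     centre = ctr)
    })
    return(list(result = resample(x, tr, ref), transform = tr))
  }
  W <- worldGrid(ref)
  d3 <- gridDim(ref)
  ux <- array(0, d3); uy <- array(0, d3); uz <- array(0, d3)
  if (kind == "intrinsic") {
    if (motion@droopAmplitudeMm == 0 && motion@bladderGrowthFraction == 0 &&
        motion@giAmplitudeMm == 0)
      return(list(result = x, field = zeroDeformationField(ref)))
    if (motion@droopAmplitudeMm > 0) {
      if (!is.null(truth) && "body" %in% structureNames(truth)) {
        ys <- W$y[structureMask(truth, "body")]
        y0 <- min(ys); y1 <- max(ys)
      } else {
        y0 <- min(W$y); y1 <- max(W$y)
      }
      # cradle contact at the lowest body line (y0): droop is zero there
      # and reaches the full amplitude at the uppermost surface.
      frac <- pmin(pmax((W$y - y0) / (y1 - y0), 0), 1)
      uy <- uy + motion@droopAmplitudeMm * frac
    }
    if (motion@bladderGrowthFraction > 0) {
      if (is.null(truth) || !"bladder" %in% structureNames(truth))
        stop("bladder filling requires truth structures with a bladder")
      bm <- structureMask(truth, "bladder")
      ctr <- maskCentroid(bm, truth)
      rb <- (3 * sum(bm) * prod(voxelSpacing(truth)) / (4 * pi))^(1 / 3)
      rs <- 2.5 * rb
      dx <- W$x - ctr[1]; dy <- W$y - ctr[2]; dz <- W$z - ctr[3]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      h <- pmax(1 - (r / rs)^2, 0)
      g <- motion@bladderGrowthFraction
      scale <- ifelse(r > 1e-9, -g * h, 0)
      ux <- ux + scale * dx; uy <- uy + scale * dy; uz <- uz + scale * dz
    }
    if (motion@giAmplitudeMm > 0) {
      if (is.null(truth) || !"bowel" %in% structureNames(truth))
        stop("GI motility requires truth structures with a bowel")
      bm <- which(structureMask(truth, "bowel"), arr.ind = TRUE)
      ctrs <- withSeed(motion@seed + 13, {
        rows <- sample(nrow(bm), min(6, nrow(bm)))
        list(pts = voxelToWorld(truth, bm[rows, , drop = FALSE]),
             dirs = matrix(rnorm(3 * length(rows)), ncol = 3))
      })
      gx <- array(0, d3); gy <- array(0, d3); gz <- array(0, d3)
      for (q in seq_len(nrow(ctrs$pts))) {
        w <- exp(-((W$x - ctrs$pts[q, 1])^2 + (W$y - ctrs$pts[q, 2])^2 +
                   (W$z - ctrs$pts[q, 3])^2) / (2 * 2.5^2))
        dn <- ctrs$dirs[q, ] / sqrt(sum(ctrs$dirs[q, ]^2))
        gx <- gx + w * dn[1]; gy <- gy + w * dn[2]; gz <- gz + w * dn[3]
      }
      mx <- max(sqrt(gx^2 + gy^2 + gz^2))
      if (mx > 0) {
        sc <- motion@giAmplitudeMm / mx
        ux <- ux + sc * gx; uy <- uy + sc * gy; uz <- uz + sc * gz
      }
    }
  } else { # mr_distortion
    if (motion@distortionAmplitudeMm == 0)
      return(list(result = x, field = zeroDeformationField(ref)))
    cf <- withSeed(motion@seed + 41, matrix(rnorm(18), nrow = 3))
    ctr <- as.numeric(voxelToWorld(ref, (gridDim(ref) + 1) / 2))
    half <- (gridDim(ref) * voxelSpacing(ref)) / 2
    xn <- (W$x - ctr[1]) / half[1]
    yn <- (W$y - ctr[2]) / half[2]
    zn <- (W$z - ctr[3]) / half[3]
    basis <- list(xn^2, yn^2, zn^2, xn * yn, xn * zn, yn * zn)
    acc <- list(array(0, d3), array(0, d3), array(0, d3))
    for (b in seq_along(basis))
      for (c in 1:3) acc[[c]] <- acc[[c]] + cf[c, b] * basis[[b]]
    mx <- max(sqrt(acc[[1]]^2 + acc[[2]]^2 + acc[[3]]^2))
    sc <- motion@distortionAmplitudeMm / mx
    ux <- sc * acc[[1]]; uy <- sc * acc[[2]]; uz <- sc * acc[[3]]
  }
  u <- array(0, c(d3, 3))
  u[, , , 1] <- ux; u[, , , 2] <- uy; u[, , , 3] <- uz
  field <- deformationField(u, imageAffine(ref))
  list(result = resample(x, field, ref), field = field)
}
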