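#' Multi-resolution rigid intensity registration
#'
#' Optimizes a rigid transform (moving-world to fixed-world) over a
#' coarse-to-fine pyramid (default 3 levels).  The default metric is
#' mutual information with 32 bins and partial-volume (linear) binning —
#' the standard multimodal choice — making the method usable for MR to CT
#' alignment; `"MIND-SSD"` minimizes the sum of squared MIND descriptor
#' differences instead.  Initialization aligns foreground intensity
#' centroids.
#'
#' @param moving,fixed [ImageVolume-class] objects with overlapping fields
#'   of view.
#' @param metric `"MI"` or `"MIND-SSD"`.
#' @param levels number of pyramid levels (downsampling by 2 per level).
#' @param nbins MI histogram bins.
#' @param init optional [RigidTransform-class] initial guess.
#' @param maxIter Nelder-Mead iteration cap per level.
#' @return a [RigidTransform-class] mapping moving-world into fixed-world.
#' @export
rigidRegisterIntensity <- function(moving, fixed, metric = c("MI", "MIND-SSD"),
                                   levels = 3, nbins = 32, init = NULL,
                                   maxIter = 400) {
  metric <- match.arg(metric)
  # overlap precondition: the moving FOV (transformed by the initial guess,
  # identity by default) must intersect the fixed FOV
  if (!.fovOverlap(moving, fixed, init))
    stop("initialization error: moving and fixed fields of view do not overlap")
  centreF <- as.numeric(voxelToWorld(fixed, (dim(fixed@voxels) + 1) / 2))
  p0 <- c(0, 0, 0, 0, 0, 0)
  if (is.null(init)) {
    cm <- .intensityCentroid(moving)
    cf <- .intensityCentroid(fixed)
    p0[4:6] <- cf - cm
  } else {
    # decompose init about centreF (angles approximated only if small;
    # otherwise keep translation exact and rotation via Euler extraction)
    p0[1:3] <- .eulerFromRotation(init@rotation)
    p0[4:6] <- as.numeric(applyRigid(init, centreF)) - centreF
  }
  toTransform <- function(p)
    rigidTransform(anglesDeg = p[1:3], translation = p[4:6],
                   centre = centreF)
  for (lev in seq(levels, 1)) {
    f <- 2^(lev - 1)
    fx <- downsampleVolume(fixed, f)
    mv <- downsampleVolume(moving, f)
    stride <- if (lev == 1) 2L else 1L
    if (metric == "MI") {
      frange <- range(fx@voxels); mrange <- range(mv@voxels)
      obj <- function(p) {
        tr <- toTransform(p)
        C <- solve(mv@affine) %*% rigidToMatrix(invertRigid(tr)) %*% fx@affine
        mi <- mi_metric_cpp(as.numeric(fx@voxels), as.integer(dim(fx@voxels)),
                            as.numeric(mv@voxels), as.integer(dim(mv@voxels)),
                            C, as.integer(nbins), frange, mrange, stride)
        if (is.na(mi)) 1e3 else -mi
      }
    } else {
      mdF <- mindDescriptor(fx)
      obj <- function(p) {
        w <- resample(mv, toTransform(p), fx)
        mdM <- mindDescriptor(w)
        mean((mdF@descriptors - mdM@descriptors)^2)
      }
    }
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = maxIter, reltol = 1e-10))
    p0 <- opt$par
  }
  toTransform(p0)
}

.intensityCentroid <- function(vol) {
  v <- vol@voxels
  thr <- mean(range(v)) * 0.25
  m <- v > thr
  if (!any(m)) m <- v > stats::median(v)
  maskCentroid(m, vol)
}

.fovOverlap <- function(moving, fixed, init = NULL) {
  corn <- function(vol) {
    d <- dim(vol@voxels)
    g <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
    voxelToWorld(vol, g)
  }
  cm <- corn(moving)
  if (!is.null(init)) cm <- applyRigid(init, cm)
  cf <- corn(fixed)
  all(apply(cm, 2, max) > apply(cf, 2, min)) &&
    all(apply(cf, 2, max) > apply(cm, 2, min))
}

.eulerFromRotation <- function(R) {
  # inverse of eulerRotation (Rz Ry Rx), degrees
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2]); rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}
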