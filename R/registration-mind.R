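#' Modality-independent neighbourhood descriptor (MIND)
#'
#' For each voxel, Gaussian-weighted patch distances to the six
#' axis-neighbours are converted to a self-similarity vector
#' `exp(-D / V)`, with `V` the mean of the six distances (floored at
#' `1e-6` of the squared dynamic range so constant images remain
#' well-defined), then normalized so the largest component is 1.  The
#' descriptor is invariant to affine intensity rescaling `v -> a*v + b`
#' (a != 0), which is what makes descriptor SSD a usable cross-modality
#' registration metric.
#'
#' @param volume an [ImageVolume-class].
#' @param sigmaVoxels patch Gaussian sigma in voxels (default 0.8).
#' @return a [MINDDescriptor-class].
#' @export
mindDescriptor <- function(volume, sigmaVoxels = 0.8) {
  if (sigmaVoxels <= 0) stop("sigma must be > 0")
  v <- volume@voxels
  d <- dim(v)
  eps <- 1e-6 * max(diff(range(v)), .Machine$double.eps)^2
  desc <- mind_cpp(as.numeric(v), as.integer(d), sigmaVoxels, eps)
  new("MINDDescriptor", descriptors = desc, dim = as.integer(d),
      affine = volume@affine, sigma = sigmaVoxels)
}

#' MIND-driven diffusion-regularized deformable registration
#'
#' Minimizes the sum of squared MIND descriptor differences between the
#' fixed image and the warped moving image with demons-style Gauss-Newton
#' updates and Gaussian (diffusion) regularization, coarse to fine.  The
#' objective is kept non-increasing across outer iterations by step
#' backtracking; a persistent objective increase raises a convergence
#' error.  Inputs are expected to be rigidly pre-aligned.
#'
#' @param moving,fixed [ImageVolume-class] objects (any modalities).
#' @param levels pyramid levels (downsampling by 2 per level).
#' @param alpha regularization weight: the field-smoothing Gaussian sigma
#'   is `3.16 * sqrt(alpha)` voxels (default alpha 0.1, about 1 voxel).
#' @param iterations per-level iteration caps (recycled).
#' @param sigmaVoxels MIND patch sigma.
#' @param stepVox maximal displacement update per iteration, voxels.
#' @return list with `field` (a [DeformationField-class] on the fixed
#'   grid; resampling `moving` through it aligns it to `fixed`) and
#'   `objective` (trace of the descriptor SSD per outer iteration).
#' @export
deformableRegisterMind <- function(moving, fixed, levels = 3, alpha = 0.1,
                                   iterations = c(60, 40, 20),
                                   sigmaVoxels = 0.8, stepVox = 0.4) {
  iterations <- rep(iterations, length.out = levels)
  sigmaReg <- 3.16 * sqrt(alpha)
  field <- NULL
  objTrace <- numeric()
  for (lev in seq(levels, 1)) {
    f <- 2^(lev - 1)
    fx <- downsampleVolume(fixed, f)
    d <- dim(fx@voxels)
    sp <- voxelSpacing(fx)
    # match the moving image's smoothing to the level's anti-alias kernel so
    # that moving == fixed yields an exactly zero residual at every level
    mv <- if (f > 1) {
      sigMov <- (f / 2.5) * voxelSpacing(fixed) / voxelSpacing(moving)
      imageVolume(array(gauss_smooth3_cpp(as.numeric(moving@voxels),
                                          as.integer(dim(moving@voxels)),
                                          sigMov), dim(moving@voxels)),
                  affine = moving@affine, modality = moving@modality,
                  frame = moving@frame)
    } else moving
    if (is.null(field)) {
      u <- array(0, c(d, 3))
    } else {
      u <- array(0, c(d, 3))
      for (c in 1:3) {
        comp <- imageVolume(field@displacements[, , , c],
                            affine = field@affine, modality = "LABEL")
        u[, , , c] <- resample(comp, NULL, fx, interpolation = "linear")@voxels
      }
    }
    mdF <- mindDescriptor(fx, sigmaVoxels)
    warpAndScore <- function(u) {
      fl <- deformationField(u, fx@affine)
      w <- resample(mv, fl, fx)
      mdM <- mindDescriptor(w, sigmaVoxels)
      resid <- mdF@descriptors - mdM@descriptors
      list(w = w, mdM = mdM, resid = resid, obj = mean(resid^2))
    }
    cur <- warpAndScore(u)
    step <- stepVox
    levelTrace <- cur$obj
    for (it in seq_len(iterations[lev])) {
      Fx <- array(0, d); Fy <- array(0, d); Fz <- array(0, d)
      for (c in seq_len(ncol(cur$resid))) {
        g <- gradient3_cpp(cur$mdM@descriptors[, c], as.integer(d), sp)
        r <- cur$resid[, c]
        Fx <- Fx + array(r * g$gx, d)
        Fy <- Fy + array(r * g$gy, d)
        Fz <- Fz + array(r * g$gz, d)
      }
      mag <- max(sqrt(Fx^2 + Fy^2 + Fz^2))
      if (mag < 1e-12) break
      sc <- step * min(sp) / mag
      uNew <- u
      uNew[, , , 1] <- u[, , , 1] + sc * Fx
      uNew[, , , 2] <- u[, , , 2] + sc * Fy
      uNew[, , , 3] <- u[, , , 3] + sc * Fz
      for (c in 1:3)
        uNew[, , , c] <- array(gauss_smooth3_cpp(as.numeric(uNew[, , , c]),
                                                 as.integer(d),
                                                 rep(sigmaReg, 3)), d)
      cand <- warpAndScore(uNew)
      if (cand$obj <= cur$obj * (1 + 1e-6)) {
        u <- uNew; cur <- cand
        levelTrace <- c(levelTrace, cur$obj)
      } else {
        step <- step / 2
        if (step < stepVox / 64) break
      }
    }
    # objective must not rise within a level (across-level values are not
    # comparable: each level has its own grid and descriptor scale)
    if (length(levelTrace) >= 2 &&
        tail(levelTrace, 1) > head(levelTrace, 1) * 1.05)
      stop(sprintf(paste("deformable registration diverged: descriptor SSD",
                         "rose from %.4g to %.4g at level %d"),
                   head(levelTrace, 1), tail(levelTrace, 1), lev))
    objTrace <- c(objTrace, levelTrace)
    field <- deformationField(u, fx@affine)
  }
  # promote the final field to the fixed grid at full resolution
  if (!all(dim(field@displacements)[1:3] == dim(fixed@voxels))) {
    u <- array(0, c(dim(fixed@voxels), 3))
    for (c in 1:3) {
      comp <- imageVolume(field@displacements[, , , c],
                          affine = field@affine, modality = "LABEL")
      u[, , , c] <- resample(comp, NULL, fixed, interpolation = "linear")@voxels
    }
    field <- deformationField(u, fixed@affine)
  }
  list(field = field, objective = objTrace)
}

#' Descriptor SSD between two images on a common grid
#'
#' The deformable objective, exposed for baseline comparisons.
#' @param a,b ImageVolumes on one grid.
#' @param sigmaVoxels MIND patch sigma.
#' @export
mindSSD <- function(a, b, sigmaVoxels = 0.8)
  mean((mindDescriptor(a, sigmaVoxels)@descriptors -
        mindDescriptor(b, sigmaVoxels)@descriptors)^2)

#' Transfer a registration chain to a co-acquired MR contrast
#'
#' The transform chain estimated between one MR contrast (e.g. bSSFP) and
#' the planning CT is applied to a second contrast acquired in the same
#' scanner session (e.g. CPMG), which is then resampled onto the CT grid so
#' that planning software can import it in place of the CT.
#'
#' @param chain list with `rigid` (a [RigidTransform-class], MR-world to
#'   CT-world) and optionally `field` (a [DeformationField-class] on the CT
#'   grid refining the rigid alignment).
#' @param target the second MR contrast ([ImageVolume-class]).
#' @param ctGrid an [ImageVolume-class] supplying the CT grid.
#' @param relative optional [RigidTransform-class] mapping the primary MR
#'   frame to `target`'s frame when the scanner stores them differently;
#'   identity when both share the frame.
#' @param primaryFrame frame tag of the contrast the chain was estimated
#'   on; must match `target@frame` unless `relative` is given.
#' @return `target` resampled onto the CT grid (linear interpolation),
#'   carrying the CT frame tag.
#' @export
transferTransform <- function(chain, target, ctGrid, relative = NULL,
                              primaryFrame = NULL) {
  if (is.null(relative)) {
    if (!is.null(primaryFrame) && !identical(primaryFrame, target@frame))
      stop("frame mismatch: chain was estimated in frame '", primaryFrame,
           "' but the target volume is in frame '", target@frame,
           "'; supply the relative transform between the two")
    relative <- rigidTransform()
  }
  rigid <- if (is.null(chain$rigid)) rigidTransform() else chain$rigid
  # target-frame point = relative(primary-frame point); the chain maps
  # primary-frame to CT, so the composed map target-frame -> CT is
  # rigid o relative^{-1}; resample pulls back through its inverse.
  composed <- composeRigid(rigid, invertRigid(relative))
  tf <- if (is.null(chain$field)) composed else
    list(rigid = composed, field = chain$field)
  out <- resample(target, tf, ctGrid, interpolation = "linear")
  out@frame <- ctGrid@frame
  out
}
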