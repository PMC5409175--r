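#' Region-growing segmentation
#'
#' The 26-connected component of voxels whose intensity lies in
#' `window`, grown from the voxel containing `seedMm`.  For the gel CT this
#' is how only the gel, and not the glass vial, is segmented: a window
#' around the gel intensity excludes both air and glass.
#'
#' @param volume an [ImageVolume-class].
#' @param seedMm world-mm seed point; its voxel intensity must lie inside
#'   the window.
#' @param window `c(lo, hi)` intensity window.
#' @param name structure name for the returned mask.
#' @return a [StructureSet-class] with a single structure.
#' @export
segmentRegionGrowing <- function(volume, seedMm, window, name = "region") {
  ijk <- round(worldToVoxel(volume, seedMm))
  d <- dim(volume@voxels)
  if (any(ijk < 1) || any(ijk > d)) stop("seed point outside the volume")
  m <- region_grow_cpp(as.numeric(volume@voxels), as.integer(d),
                       as.integer(ijk - 1L), window[1], window[2])
  structureSet(array(as.integer(m), d), volume@affine,
               stats::setNames(1L, name))
}

#' Convert a mask surface to a point cloud
#'
#' Boundary voxels of the mask are found with 6-connectivity; the surface
#' area is estimated from the gradient magnitude of the smoothed mask
#' (a Coarea-formula estimate, accurate for smooth surfaces), and
#' `area / spacing^2` points are drawn from the boundary voxel centres with
#' systematic (deterministic) sampling, giving approximately uniform
#' density.  Every point lies within one voxel diagonal of the true
#' surface.
#'
#' @param mask a [StructureSet-class] (first structure used) or logical
#'   array plus `affine`.
#' @param spacingMm target inter-point spacing, mm.
#' @param name structure to use when `mask` is a StructureSet.
#' @param affine required when `mask` is a plain array.
#' @return a [PointCloud-class].
#' @export
maskToSurfacePoints <- function(mask, spacingMm = 1, name = NULL,
                                affine = NULL) {
  if (is(mask, "StructureSet")) {
    nm <- if (is.null(name)) structureNames(mask)[1] else name
    arr <- structureMask(mask, nm)
    affine <- mask@affine
  } else {
    arr <- mask
    if (is.null(affine)) stop("affine required for a plain mask array")
  }
  if (!any(arr)) stop("empty mask has no surface")
  d <- dim(arr)
  b <- array(boundary_mask_cpp(as.logical(arr), as.integer(d)), d)
  idx <- which(b, arr.ind = TRUE)
  ref <- structureSet(array(0L, d), affine, integer())
  pts <- voxelToWorld(ref, idx)
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  sm <- gauss_smooth3_cpp(as.numeric(arr), as.integer(d), rep(1.2, 3))
  g <- gradient3_cpp(sm, as.integer(d), sp)
  gm <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  area <- sum(gm) * prod(sp)
  lin <- (idx[, 3] - 1) * d[1] * d[2] + (idx[, 2] - 1) * d[1] + idx[, 1]
  nrm <- -cbind(g$gx[lin], g$gy[lin], g$gz[lin]) # outward (mask gradient
  nn <- sqrt(rowSums(nrm^2))                     # points inward)
  nn[nn < 1e-12] <- 1
  nrm <- nrm / nn
  nTarget <- max(4L, round(area / spacingMm^2))
  if (nTarget < nrow(pts)) {
    ord <- order(idx[, 3], idx[, 2], idx[, 1])
    keep <- ord[round(seq(1, length(ord), length.out = nTarget))]
    pts <- pts[keep, , drop = FALSE]
    nrm <- nrm[keep, , drop = FALSE]
  }
  pointCloud(pts, nrm)
}

#' Iterative closest point rigid registration
#'
#' Alternates closest-point matching (moving to fixed) with a rigid
#' least-squares update, optionally trimming the worst-matched fraction of
#' pairs, until convergence (`tolMm`) or `maxIter`.  Two update rules are
#' provided: `"point_to_plane"` (default; a linearized least-squares fit
#' of the residuals along the fixed surface normals, which converges
#' reliably on surfaces with sliding near-symmetries such as a gel
#' cylinder with a tilted meniscus) and `"point_to_point"` (the classic
#' Kabsch/SVD update).  Point-to-plane requires normals on the fixed
#' cloud ([maskToSurfacePoints()] provides them); without normals the
#' method falls back to point-to-point.
#'
#' Initialization aligns centroids and, optionally, principal axes (signs
#' disambiguated by the third moment along each axis; skipped for nearly
#' degenerate axes, as for an almost-cylindrical vial).
#'
#' @param moving,fixed [PointCloud-class] objects (world mm).
#' @param maxIter iteration cap.
#' @param tolMm convergence tolerance (RMS change, and parameter-update
#'   size for point-to-plane).
#' @param trim fraction of worst pairs discarded each iteration (0 to 0.5).
#' @param method `"point_to_plane"` or `"point_to_point"`.
#' @param init `"centroid"` (default) or `"pca"`.
#' @param qualityWarnMm optional RMS level (e.g. 3 voxel sizes) above which
#'   a registration-quality warning is raised instead of failing.
#' @return list with `transform` (a [RigidTransform-class] mapping
#'   moving-world to fixed-world), `rmsMm` (final Euclidean RMS over the
#'   kept pairs), `iterations`, `converged`.
#' @export
icpRegister <- function(moving, fixed, maxIter = 200, tolMm = 1e-4,
                        trim = 0, method = c("point_to_plane",
                                             "point_to_point"),
                        init = c("centroid", "pca"), qualityWarnMm = NULL) {
  init <- match.arg(init)
  method <- match.arg(method)
  M <- moving@points; Fx <- fixed@points
  if (nrow(M) < 3 || nrow(Fx) < 3)
    stop("point clouds need at least 3 points for rigid registration")
  Nf <- fixed@normals
  if (method == "point_to_plane" && !nrow(Nf)) method <- "point_to_point"
  cm <- colMeans(M); cf <- colMeans(Fx)
  R <- diag(3)
  if (init == "pca") {
    fr <- function(P) {
      e <- eigen(stats::cov(P), symmetric = TRUE)
      V <- e$vectors
      ctr <- sweep(P, 2, colMeans(P))
      for (c in 1:3) {
        sk <- mean((ctr %*% V[, c])^3)
        if (sk < 0) V[, c] <- -V[, c]
      }
      if (det(V) < 0) V[, 3] <- -V[, 3]
      list(V = V, ev = e$values)
    }
    fm <- fr(M); ff <- fr(Fx)
    # only align axes that are non-degenerate (eigengap over 10%)
    if (min(abs(diff(fm$ev)) / max(fm$ev)) > 0.1)
      R <- ff$V %*% t(fm$V)
  }
  t <- cf - as.numeric(R %*% cm)
  rmsPrev <- Inf; rms <- Inf; it <- 0; converged <- FALSE
  nKeep <- max(3L, round(nrow(M) * (1 - trim)))
  for (it in seq_len(maxIter)) {
    Mt <- sweep(M %*% t(R), 2, t, "+")
    nn <- nn_match_cpp(Mt, Fx)
    keep <- if (nKeep < nrow(M)) order(nn$distance)[seq_len(nKeep)] else
      seq_len(nrow(M))
    P <- Mt[keep, , drop = FALSE]
    Q <- Fx[nn$index[keep], , drop = FALSE]
    rms <- sqrt(mean(rowSums((P - Q)^2)))
    if (method == "point_to_plane") {
      Np <- Nf[nn$index[keep], , drop = FALSE]
      b <- rowSums((Q - P) * Np)
      J <- cbind(P[, 2] * Np[, 3] - P[, 3] * Np[, 2],
                 P[, 3] * Np[, 1] - P[, 1] * Np[, 3],
                 P[, 1] * Np[, 2] - P[, 2] * Np[, 1], Np)
      fit <- tryCatch(qr.solve(crossprod(J) + 1e-12 * diag(6),
                               crossprod(J, b)),
                      error = function(e) {
                        warning("rank-deficient (collinear) point geometry")
                        rep(0, 6)
                      })
      w <- fit[1:3]; dt <- fit[4:6]
      th <- sqrt(sum(w^2))
      dR <- if (th < 1e-14) diag(3) else {
        k <- w / th
        K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
        diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      }
      R <- dR %*% R
      sv <- svd(R); R <- sv$u %*% t(sv$v)
      t <- as.numeric(dR %*% t + dt)
      if (th + sqrt(sum(dt^2)) < tolMm) { converged <- TRUE; break }
    } else {
      P0 <- M[keep, , drop = FALSE]
      cp <- colMeans(P0); cq <- colMeans(Q)
      H <- crossprod(sweep(P0, 2, cp), sweep(Q, 2, cq))
      sv <- svd(H)
      if (sv$d[2] < 1e-6 * sv$d[1])
        warning("nearly collinear point geometry: rigid fit is rank-deficient")
      S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
      R <- sv$v %*% S %*% t(sv$u)
      t <- cq - as.numeric(R %*% cp)
      Pn <- sweep(P0 %*% t(R), 2, t, "+")
      rms <- sqrt(mean(rowSums((Pn - Q)^2)))
      if (abs(rmsPrev - rms) < tolMm) { converged <- TRUE; break }
      rmsPrev <- rms
    }
  }
  tr <- rigidTransform(rotation = R, translation = t)
  if (!is.null(qualityWarnMm) && is.finite(rms) && rms > qualityWarnMm)
    warning(sprintf(paste("final ICP RMS %.3f mm exceeds the quality bound",
                          "%.3f mm: possible local minimum from",
                          "near-symmetric geometry"), rms, qualityWarnMm))
  list(transform = tr, rmsMm = rms, iterations = it, converged = converged)
}

#' Dice coefficient of two logical masks
#' @param a,b logical arrays on a common grid.
#' @export
diceCoefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
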