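# Shared fixtures, built once per test run at coarse working resolutions.

.fixtures <- new.env()

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

coarseGelSpec <- function() gelPhantomSpec(ctSpacingMm = 0.35,
                                           mrSpacingMm = 0.4)

coarseGel <- function() memo("gel", makeGelPhantom(coarseGelSpec()))

coarseMouseSpec <- function(...) mousePhantomSpec(ctSpacingMm = 0.5,
                                                  mrSpacingMm = 0.5, ...)

coarseMouse <- function() memo("mouse", makeMousePhantom(coarseMouseSpec()))

coarseMouseClean <- function()
  memo("mouseClean", makeMousePhantom(coarseMouseSpec(), noise = FALSE))

# homogeneous water-equivalent cylinder (axis along y) in an air box
waterCylinder <- function(n = c(80, 80, 80), spacing = 0.4, radius = 14,
                          halfHeight = 15) {
  ref <- imageVolume(array(0, n), spacing = rep(spacing, 3),
                     origin = -n * spacing / 2 + spacing / 2)
  W <- worldGrid(ref)
  arr <- array(0, n)
  arr[W$x^2 + W$z^2 < radius^2 & abs(W$y) < halfHeight] <- 1000
  imageVolume(arr, affine = imageAffine(ref))
}

randomRigid <- function(maxRotDeg, maxTransMm) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  a <- runif(1, 0.1, 1) * maxRotDeg * pi / 180
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  rigidTransform(rotation = diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K),
                 translation = runif(3, -1, 1) * maxTransMm)
}

rotationOf <- function(axis, angleDeg) {
  ax <- axis / sqrt(sum(axis^2)); a <- angleDeg * pi / 180
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# maximum point-mapping discrepancy of two rigid transforms over test points
transformDiscrepancyMm <- function(a, b, pts) {
  max(sqrt(rowSums((applyRigid(a, pts) - applyRigid(b, pts))^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
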