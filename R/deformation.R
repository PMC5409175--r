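#' Construct a DeformationField
#' @param displacements 4D array (nx, ny, nz, 3), world-mm displacements
#'   (backward convention: added to the grid point before sampling).
#' @param affine the grid's voxel-to-world matrix.
#' @export
deformationField <- function(displacements, affine)
  new("DeformationField", displacements = displacements, affine = affine)

#' Zero deformation field on a reference grid
#' @param reference object with grid and affine.
#' @export
zeroDeformationField <- function(reference)
  deformationField(array(0, c(gridDim(reference), 3)),
                   imageAffine(reference))

#' Displacement magnitude volume of a field
#' @param field a [DeformationField-class].
#' @export
fieldMagnitude <- function(field) {
  u <- field@displacements
  m <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  imageVolume(m, affine = field@affine, modality = "LABEL", frame = "world")
}

# Vectorized trilinear sampling of a 3D array at continuous 1-based voxel
# coordinates (n x 3); values outside the grid take `fill`.
trilinearAt <- function(arr, ijk, fill = 0) {
  d <- dim(arr)
  ijk <- rbind(ijk) - 1 # to 0-based
  out <- rep(fill, nrow(ijk))
  ok <- ijk[, 1] > -0.5 & ijk[, 2] > -0.5 & ijk[, 3] > -0.5 &
        ijk[, 1] < d[1] - 0.5 & ijk[, 2] < d[2] - 0.5 & ijk[, 3] < d[3] - 0.5
  if (!any(ok)) return(out)
  p <- ijk[ok, , drop = FALSE]
  p[, 1] <- pmin(pmax(p[, 1], 0), d[1] - 1)
  p[, 2] <- pmin(pmax(p[, 2], 0), d[2] - 1)
  p[, 3] <- pmin(pmax(p[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(p), rep(d - 2, each = nrow(p)))
  i0 <- pmax(i0, 0)
  f <- p - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
         (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
         (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    idx <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    acc <- acc + w * arr[idx]
  }
  out[ok] <- acc
  out
}

#' Sample a volume at world-mm points (trilinear)
#' @param vol an ImageVolume.
#' @param pts n x 3 world coordinates.
#' @param fill out-of-field value.
#' @export
sampleAtWorld <- function(vol, pts, fill = 0)
  trilinearAt(vol@voxels, worldToVoxel(vol, pts), fill)

#' Evaluate a deformation field at world points
#' @param field a [DeformationField-class].
#' @param pts n x 3 world coordinates.
#' @return n x 3 displacement matrix (mm).
#' @export
fieldAtWorld <- function(field, pts) {
  ref <- field
  ijk <- worldToVoxel(field, pts)
  sapply(1:3, function(c) trilinearAt(field@displacements[, , , c], ijk))
}

#' Numerically invert a deformation field (fixed-point iteration)
#'
#' Finds v with v(x) = -u(x + v(x)); composing the field with its inverse
#' is the identity up to interpolation error for smooth fields.
#'
#' @param field a [DeformationField-class].
#' @param iterations fixed-point iterations.
#' @export
invertDeformationField <- function(field, iterations = 15) {
  d <- dim(field@displacements)
  grid <- deformationField(array(0, d), field@affine)
  W <- worldGrid(field)
  pts <- cbind(as.numeric(W$x), as.numeric(W$y), as.numeric(W$z))
  v <- matrix(0, nrow(pts), 3)
  for (it in seq_len(iterations))
    v <- -fieldAtWorld(field, pts + v)
  u <- array(0, d)
  for (c in 1:3) u[, , , c] <- array(v[, c], d[1:3])
  deformationField(u, field@affine)
}
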