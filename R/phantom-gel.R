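#' Specification of a digital polymer-gel dosimeter vial
#'
#' A radiologically water-equivalent gel column inside a glass vial.  The
#' vials are prepared tilted so the set meniscus is not horizontal: a
#' nonzero `meniscusTiltDeg` makes the gel volume rotationally asymmetric
#' about the vial axis (vertical, +y), which is what lets a surface-driven
#' registration lock the rotation without fiducials.
#'
#' @slot vialInnerDiameterMm inner diameter of the vial (default 25).
#' @slot gelHeightMm gel column height at the vial axis.
#' @slot meniscusTiltDeg tilt of the meniscus plane, degrees.
#' @slot wallThicknessMm glass wall thickness.
#' @slot ctSpacingMm,mrSpacingMm isotropic voxel spacings per modality.
#' @slot ctNoiseSigma Gaussian CT noise sd (CT number units).
#' @slot mrSNR Rician MR signal-to-noise ratio on the raw gel signal.
#' @slot seed integer random seed for the noise draws.
#' @export
setClass("GelPhantomSpec",
  representation(vialInnerDiameterMm = "numeric", gelHeightMm = "numeric",
                 meniscusTiltDeg = "numeric", wallThicknessMm = "numeric",
                 ctSpacingMm = "numeric", mrSpacingMm = "numeric",
                 ctNoiseSigma = "numeric", mrSNR = "numeric",
                 seed = "numeric"),
  prototype(vialInnerDiameterMm = 25, gelHeightMm = 18, meniscusTiltDeg = 15,
            wallThicknessMm = 1.2, ctSpacingMm = 0.16, mrSpacingMm = 0.27,
            ctNoiseSigma = 20, mrSNR = 20, seed = 1))

#' @rdname GelPhantomSpec-class
#' @param ... slot values overriding the defaults.
#' @export
gelPhantomSpec <- function(...) new("GelPhantomSpec", ...)

# Renderer intensity scales (water-equivalent CT scale; arbitrary MR units)
.gelCT <- c(air = 0, gel = 1000, glass = 2000)
.gelMRSignal <- 400

# Analytic gel/vial membership at arbitrary object-frame points.
.gelMasks <- function(px, py, pz, spec) {
  ri <- spec@vialInnerDiameterMm / 2
  ro <- ri + spec@wallThicknessMm
  w <- spec@wallThicknessMm
  h <- spec@gelHeightMm
  tt <- tan(spec@meniscusTiltDeg * pi / 180)
  r2 <- px * px + pz * pz
  gel <- r2 < ri^2 & py >= 0 & py <= h + tt * px
  vial <- (r2 >= ri^2 & r2 < ro^2 & py >= -w & py <= h + abs(tt) * ri + 6) |
          (r2 < ro^2 & py >= -w & py < 0)
  list(gel = gel, vial = vial)
}

.gelGrid <- function(spacing) {
  fov <- c(32, 32, 32)          # mm; x/z centred on the vial axis, y from -4
  origin <- c(-16, -4, -16)
  n <- round(fov / spacing)
  list(n = n, origin = origin + spacing / 2, spacing = spacing)
}

.axisGridVolume <- function(g, modality, frame = "world") {
  imageVolume(array(0, g$n), spacing = rep(g$spacing, 3), origin = g$origin,
              modality = modality, frame = frame)
}

#' Generate a digital gel-vial phantom in CT and MR renderings
#'
#' The CT rendering shows both the gel and the glass vial wall (distinct
#' intensities); the MR rendering shows the gel only.  An optional rigid
#' `pose` (object frame to MR-scanner frame) emulates repositioning of the
#' vial between the irradiator and the MR scanner; the MR volume is then
#' rendered in the scanner frame.
#'
#' @param spec a [GelPhantomSpec-class].
#' @param pose optional [RigidTransform-class]: object (CT) frame to MR
#'   frame.  Default identity.
#' @param noise add the spec's imaging noise (seeded, deterministic).
#' @return list with `ct`, `mr` (noisy renderings), `ctClean`, `mrClean`,
#'   `truth` (StructureSet on the CT grid: gel=1, vial=2), `truthMR`
#'   (same structures on the MR grid, in the MR frame), and `pose`.
#' @export
makeGelPhantom <- function(spec = gelPhantomSpec(), pose = NULL,
                           noise = TRUE) {
  if (is.null(pose)) pose <- rigidTransform()
  gct <- .gelGrid(spec@ctSpacingMm)
  ct <- .axisGridVolume(gct, "CT", frame = "irradiator")
  W <- worldGrid(ct)
  m <- .gelMasks(W$x, W$y, W$z, spec)
  ctArr <- array(.gelCT["air"], gct$n)
  ctArr[m$gel] <- .gelCT["gel"]
  ctArr[m$vial] <- .gelCT["glass"]
  ctClean <- imageVolume(ctArr, affine = ct@affine, modality = "CT",
                         frame = "irradiator")
  labels <- array(0L, gct$n)
  labels[m$gel] <- 1L; labels[m$vial] <- 2L
  meta <- list()
  if (spec@meniscusTiltDeg == 0)
    meta$warnings <- paste("meniscus tilt is zero: the gel is rotationally",
                           "symmetric about the vial axis and surface",
                           "registration cannot recover axial rotation")
  truth <- structureSet(labels, ct@affine, c(gel = 1, vial = 2),
                        metadata = meta)

  gmr <- .gelGrid(spec@mrSpacingMm)
  mr <- .axisGridVolume(gmr, "MR_CEFAST", frame = "scanner")
  Wm <- worldGrid(mr)
  inv <- invertRigid(pose)
  pobj <- applyRigid(inv, cbind(as.numeric(Wm$x), as.numeric(Wm$y),
                                as.numeric(Wm$z)))
  mm <- .gelMasks(array(pobj[, 1], gmr$n), array(pobj[, 2], gmr$n),
                  array(pobj[, 3], gmr$n), spec)
  mrArr <- array(0, gmr$n)
  mrArr[mm$gel] <- .gelMRSignal
  mrClean <- imageVolume(mrArr, affine = mr@affine, modality = "MR_CEFAST",
                         frame = "scanner")
  labMR <- array(0L, gmr$n)
  labMR[mm$gel] <- 1L; labMR[mm$vial] <- 2L
  truthMR <- structureSet(labMR, mr@affine, c(gel = 1, vial = 2),
                          metadata = meta)

  out <- list(ctClean = ctClean, mrClean = mrClean, truth = truth,
              truthMR = truthMR, pose = pose, spec = spec)
  if (noise) {
    out$ct <- addImageNoise(ctClean, "gaussian", spec@ctNoiseSigma,
                            seed = spec@seed)
    out$mr <- addImageNoise(mrClean, "rician", .gelMRSignal / spec@mrSNR,
                            seed = spec@seed + 7919)
  } else {
    out$ct <- ctClean
    out$mr <- mrClean
  }
  out
}

#' Default gel dose-response parameters
#'
#' Saturating exponential signal change
#' `dS(D) = sMax * (1 - exp(-k * max(D - visibilityGy, 0)))`:
#' monotone in dose, zero below the visibility threshold, and with the
#' default `k` the 2 Gy beam paths and the 4 Gy intersection are separated
#' by well over 3 noise standard deviations at SNR 20.
#' @export
gelResponse <- function(sMax = 600, k = 0.35, visibilityGy = 1)
  list(sMax = sMax, k = k, visibilityGy = visibilityGy)

#' Virtual gel-dosimeter MR readout after irradiation
#'
#' Adds the dose-dependent signal change to a pre-irradiation gel MR
#' rendering.  The gel polymerizes in proportion to absorbed dose; the
#' resulting signal change is monotone and saturating.
#'
#' @param mr pre-irradiation gel MR rendering (noise-free for a clean
#'   readout chain; add noise afterwards with [addImageNoise()]).
#' @param dose a [DoseGrid-class] on the same grid as `mr`.
#' @param response parameters from [gelResponse()].
#' @param gelMask logical array restricting the response to gel voxels;
#'   defaults to `mr > 0.3 * max(mr)`.
#' @return ImageVolume with the post-irradiation signal.
#' @export
gelMRAfterDose <- function(mr, dose, response = gelResponse(),
                           gelMask = NULL) {
  if (!all(dim(mr@voxels) == dim(dose@voxels)) ||
      max(abs(mr@affine - dose@affine)) > 1e-6)
    stop("dose must share the MR grid")
  if (any(dose@voxels < 0)) stop("negative dose is not physical")
  if (is.null(gelMask)) gelMask <- mr@voxels > 0.3 * max(mr@voxels)
  dEff <- pmax(dose@voxels - response$visibilityGy, 0)
  dS <- response$sMax * (1 - exp(-response$k * dEff))
  dS[!gelMask] <- 0
  imageVolume(mr@voxels + dS, affine = mr@affine, modality = mr@modality,
              frame = mr@frame)
}
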