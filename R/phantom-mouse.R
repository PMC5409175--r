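#' Specification of a labelled abdominal mouse phantom
#'
#' A supine mouse abdomen built from analytic shapes: a tapered
#' superellipse body, ellipsoidal organs (liver, stomach, spleen, kidneys,
#' adrenals of 1.5-3 mm diameter, bladder), a coiled bowel tube and a
#' pancreatic-style tumour in the upper right abdomen.  The per-modality
#' contrast table makes the soft-tissue organs nearly invisible in the CT
#' rendering (span below 30 CT units against sigma 20 noise) while the MR
#' renderings carry strong organ contrast; the CPMG rendering gives the
#' highest tumour-to-normal-tissue contrast.
#'
#' World frame: +x right, +y anterior (up, beam zero direction is -y),
#' +z superior; the body axis lies along z.
#'
#' @slot organs named list of organ geometries (ellipsoids: `centre`,
#'   `semiAxes`; bladder radius; bowel tube path parameters).
#' @slot tumourDiameterMm tumour diameter (default 4.8 mm).
#' @slot contrast named list of per-modality intensity tables (named numeric
#'   vectors per structure).
#' @slot ctSpacingMm,mrSpacingMm isotropic voxel spacings.
#' @slot ctNoiseSigma Gaussian CT noise sd.
#' @slot mrSNR Rician MR SNR on the body-tissue signal.
#' @slot seed integer seed for the noise draws.
#' @export
setClass("MousePhantomSpec",
  representation(organs = "list", tumourDiameterMm = "numeric",
                 contrast = "list", ctSpacingMm = "numeric",
                 mrSpacingMm = "numeric", ctNoiseSigma = "numeric",
                 mrSNR = "numeric", seed = "numeric"))

.defaultOrgans <- function(tumourDiameterMm = 4.8) list(
  body     = list(a = 11, b = 9, halfLengthZ = 19),
  liver    = list(centre = c(0, 2, 12),      semiAxes = c(7.5, 4.5, 4.5)),
  stomach  = list(centre = c(-4.5, 1, 3.5),  semiAxes = c(3, 2.6, 3)),
  spleen   = list(centre = c(-8.5, -1, 5.5), semiAxes = c(1.4, 1.4, 4.5)),
  kidney_L = list(centre = c(-5.5, -3, -1),  semiAxes = c(2.2, 1.8, 3.2)),
  kidney_R = list(centre = c(5.5, -3, 1),    semiAxes = c(2.2, 1.8, 3.2)),
  adrenal_L = list(centre = c(-5.3, -3, 3.8), semiAxes = c(1, 1, 1.2)),
  adrenal_R = list(centre = c(5.3, -3, 6),    semiAxes = c(1, 1, 1.2)),
  bladder  = list(centre = c(0, -2.5, -15.5), semiAxes = rep(2.5, 3)),
  tumour   = list(centre = c(4.5, 2, 4),
                  semiAxes = rep(tumourDiameterMm / 2, 3)),
  bowel    = list(radiusMm = 1.4, nKnots = 81))

.defaultContrast <- list(
  CT = c(background = 0, body = 1000, liver = 1020, stomach = 990,
         bowel = 1005, spleen = 1015, kidney_L = 1010, kidney_R = 1010,
         adrenal_L = 1005, adrenal_R = 1005, bladder = 995, tumour = 1005),
  MR_bSSFP = c(background = 0, body = 300, liver = 350, stomach = 650,
               bowel = 450, spleen = 500, kidney_L = 600, kidney_R = 600,
               adrenal_L = 800, adrenal_R = 800, bladder = 950,
               tumour = 500),
  MR_CPMG = c(background = 0, body = 200, liver = 230, stomach = 400,
              bowel = 350, spleen = 320, kidney_L = 380, kidney_R = 380,
              adrenal_L = 420, adrenal_R = 420, bladder = 500,
              tumour = 750))

#' @rdname MousePhantomSpec-class
#' @param tumourDiameterMm tumour diameter in mm (KPC-entry tumours are
#'   identified at about 4-5 mm).
#' @param ... further slot overrides.
#' @export
mousePhantomSpec <- function(tumourDiameterMm = 4.8, ctSpacingMm = 0.16,
                             mrSpacingMm = 0.25, ctNoiseSigma = 20,
                             mrSNR = 20, seed = 1, organs = NULL,
                             contrast = NULL) {
  if (is.null(organs)) organs <- .defaultOrgans(tumourDiameterMm)
  if (is.null(contrast)) contrast <- .defaultContrast
  new("MousePhantomSpec", organs = organs,
      tumourDiameterMm = tumourDiameterMm, contrast = contrast,
      ctSpacingMm = ctSpacingMm, mrSpacingMm = mrSpacingMm,
      ctNoiseSigma = ctNoiseSigma, mrSNR = mrSNR, seed = seed)
}

.mouseLabelTable <- c(body = 1, liver = 2, stomach = 3, bowel = 4,
                      spleen = 5, kidney_L = 6, kidney_R = 7, adrenal_L = 8,
                      adrenal_R = 9, bladder = 10, tumour = 11)

.bowelPath <- function(n) {
  t <- seq(0, 1, length.out = n)
  cbind(4.2 * cos(4 * pi * t) * (1 - 0.25 * t),
        -0.5 + 1.6 * sin(4 * pi * t),
        -3.5 - 8.5 * t)
}

# Rasterize organ labels at arbitrary object-frame points.
# Errors on overlapping organs, naming the colliding pair.
.mouseLabels <- function(px, py, pz, spec) {
  og <- spec@organs
  d <- dim(px)
  body <- og$body
  s2 <- pmax(0, 1 - (pz / body$halfLengthZ)^4)
  inBody <- (px / body$a)^2 + (py / body$b)^2 <= s2
  lab <- array(0L, d)
  lab[inBody] <- .mouseLabelTable[["body"]]
  assign1 <- function(lab, mask, name) {
    hit <- lab[mask]
    clash <- hit != 0L & hit != .mouseLabelTable[["body"]]
    if (any(clash)) {
      other <- names(.mouseLabelTable)[match(hit[clash][1], .mouseLabelTable)]
      stop("overlapping organs in phantom spec: ", name, " and ", other)
    }
    if (any(hit == 0L))
      stop("organ '", name, "' extends outside the body")
    lab[mask] <- .mouseLabelTable[[name]]
    lab
  }
  ell <- function(gname) {
    o <- og[[gname]]
    ((px - o$centre[1]) / o$semiAxes[1])^2 +
      ((py - o$centre[2]) / o$semiAxes[2])^2 +
      ((pz - o$centre[3]) / o$semiAxes[3])^2 <= 1
  }
  for (nm in c("liver", "stomach", "spleen", "kidney_L", "kidney_R",
               "adrenal_L", "adrenal_R", "bladder", "tumour"))
    lab <- assign1(lab, ell(nm), nm)
  # bowel: tube of spheres along the coiled path, computed on a subvolume
  bw <- og$bowel
  path <- .bowelPath(bw$nKnots)
  r <- bw$radiusMm
  box <- which(pz > min(path[, 3]) - r - 0.5 & pz < max(path[, 3]) + r + 0.5 &
               abs(px) < max(abs(path[, 1])) + r + 0.5 &
               py > min(path[, 2]) - r - 0.5 & py < max(path[, 2]) + r + 0.5)
  if (length(box)) {
    bx <- px[box]; by <- py[box]; bz <- pz[box]
    inTube <- rep(FALSE, length(box))
    for (q in seq_len(nrow(path)))
      inTube <- inTube | ((bx - path[q, 1])^2 + (by - path[q, 2])^2 +
                          (bz - path[q, 3])^2 <= r^2)
    mask <- array(FALSE, d)
    mask[box[inTube]] <- TRUE
    lab <- assign1(lab, mask, "bowel")
  }
  lab
}

.mouseGrid <- function(spacing) {
  fov <- c(28, 24, 44)
  origin <- -fov / 2
  n <- round(fov / spacing)
  list(n = n, origin = origin + spacing / 2, spacing = spacing)
}

.renderFromLabels <- function(lab, table, affine, modality, frame) {
  arr <- array(table[["background"]], dim(lab))
  for (nm in names(.mouseLabelTable)) {
    m <- lab == .mouseLabelTable[[nm]]
    if (any(m)) arr[m] <- table[[nm]]
  }
  imageVolume(arr, affine = affine, modality = modality, frame = frame)
}

#' Generate the labelled mouse phantom in CT, bSSFP and CPMG renderings
#'
#' @param spec a [MousePhantomSpec-class].
#' @param pose optional [RigidTransform-class] from the object (CT/irradiator)
#'   frame to the MR scanner frame; both MR contrasts share it.
#' @param noise add seeded imaging noise.
#' @return list with `ct`, `bssfp`, `cpmg` (+ `*Clean` versions), `truth`
#'   (StructureSet on the CT grid), `truthMR` (on the MR grid), `pose`.
#' @export
makeMousePhantom <- function(spec = mousePhantomSpec(), pose = NULL,
                             noise = TRUE) {
  if (is.null(pose)) pose <- rigidTransform()
  gct <- .mouseGrid(spec@ctSpacingMm)
  ctRef <- .axisGridVolume(gct, "CT", frame = "irradiator")
  W <- worldGrid(ctRef)
  labCT <- .mouseLabels(W$x, W$y, W$z, spec)
  truth <- structureSet(labCT, ctRef@affine, .mouseLabelTable)
  ctClean <- .renderFromLabels(labCT, spec@contrast$CT, ctRef@affine, "CT",
                               "irradiator")

  gmr <- .mouseGrid(spec@mrSpacingMm)
  mrRef <- .axisGridVolume(gmr, "MR_bSSFP", frame = "scanner")
  Wm <- worldGrid(mrRef)
  pobj <- applyRigid(invertRigid(pose),
                     cbind(as.numeric(Wm$x), as.numeric(Wm$y),
                           as.numeric(Wm$z)))
  labMR <- .mouseLabels(array(pobj[, 1], gmr$n), array(pobj[, 2], gmr$n),
                        array(pobj[, 3], gmr$n), spec)
  truthMR <- structureSet(labMR, mrRef@affine, .mouseLabelTable)
  bssfpClean <- .renderFromLabels(labMR, spec@contrast$MR_bSSFP,
                                  mrRef@affine, "MR_bSSFP", "scanner")
  cpmgClean <- .renderFromLabels(labMR, spec@contrast$MR_CPMG,
                                 mrRef@affine, "MR_CPMG", "scanner")

  out <- list(ctClean = ctClean, bssfpClean = bssfpClean,
              cpmgClean = cpmgClean, truth = truth, truthMR = truthMR,
              pose = pose, spec = spec)
  if (noise) {
    out$ct <- addImageNoise(ctClean, "gaussian", spec@ctNoiseSigma,
                            seed = spec@seed)
    out$bssfp <- addImageNoise(bssfpClean, "rician",
                               spec@contrast$MR_bSSFP[["body"]] / spec@mrSNR,
                               seed = spec@seed + 104729)
    out$cpmg <- addImageNoise(cpmgClean, "rician",
                              spec@contrast$MR_CPMG[["body"]] / spec@mrSNR,
                              seed = spec@seed + 224737)
  } else {
    out$ct <- ctClean; out$bssfp <- bssfpClean; out$cpmg <- cpmgClean
  }
  out
}

#' Equivalent-sphere diameter of a structure
#' @param truth StructureSet.
#' @param name structure name.
#' @export
equivalentSphereDiameterMm <- function(truth, name) {
  v <- sum(structureMask(truth, name)) * prod(voxelSpacing(truth))
  2 * (3 * v / (4 * pi))^(1 / 3)
}
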