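test_that("gel phantom renders the vial in CT but not in MR", {
  ph <- coarseGel()
  vialCT <- structureMask(ph$truth, "vial")
  gelCT <- structureMask(ph$truth, "gel")
  expect_gt(mean(voxels(ph$ctClean)[vialCT]), 1900)   # glass
  expect_equal(unique(voxels(ph$ctClean)[gelCT]), 1000)
  vialMR <- structureMask(ph$truthMR, "vial")
  expect_true(all(voxels(ph$mrClean)[vialMR] == 0))
  expect_true(all(voxels(ph$mrClean)[structureMask(ph$truthMR, "gel")] > 0))
})

test_that("meniscus tilt controls rotational asymmetry about the vial axis", {
  # RMS distance of the 90-degree-rotated gel surface to the gel boundary,
  # measured against the analytic geometry (signed distance of the
  # cylinder/meniscus/bottom intersection)
  rmsAfter90 <- function(tiltDeg) {
    sp <- gelPhantomSpec(ctSpacingMm = 0.35, mrSpacingMm = 0.5,
                         meniscusTiltDeg = tiltDeg)
    ph <- makeGelPhantom(sp, noise = FALSE)
    pc <- maskToSurfacePoints(ph$truth, 1, name = "gel")
    rot <- pc@points %*% t(rotationOf(c(0, 1, 0), 90))
    ri <- sp@vialInnerDiameterMm / 2
    tt <- tan(tiltDeg * pi / 180)
    sdf <- pmax(sqrt(rot[, 1]^2 + rot[, 3]^2) - ri,
                (rot[, 2] - sp@gelHeightMm - tt * rot[, 1]) /
                  sqrt(1 + tt^2),
                -rot[, 2])
    sqrt(mean(sdf^2))
  }
  vox <- 0.35
  expect_gt(rmsAfter90(15), 2 * vox)   # asymmetric when tilted
  expect_lt(rmsAfter90(0), 0.5 * vox)  # symmetric when flat
  # zero tilt records a warning in the truth metadata
  ph0 <- makeGelPhantom(gelPhantomSpec(ctSpacingMm = 0.5, mrSpacingMm = 0.6,
                                       meniscusTiltDeg = 0), noise = FALSE)
  expect_match(ph0$truth@metadata$warnings, "symmetric")
})

test_that("phantom generation is deterministic for a fixed seed", {
  sp <- gelPhantomSpec(ctSpacingMm = 0.6, mrSpacingMm = 0.7, seed = 11)
  a <- makeGelPhantom(sp)
  b <- makeGelPhantom(sp)
  expect_identical(voxels(a$ct), voxels(b$ct))
  expect_identical(voxels(a$mr), voxels(b$mr))
  msp <- mousePhantomSpec(ctSpacingMm = 0.8, mrSpacingMm = 0.8, seed = 4)
  ma <- makeMousePhantom(msp)
  mb <- makeMousePhantom(msp)
  expect_identical(voxels(ma$bssfp), voxels(mb$bssfp))
  expect_identical(voxels(ma$ct), voxels(mb$ct))
})

test_that("mouse phantom has the CT-invisible, MR-visible contrast dichotomy", {
  ph <- coarseMouse()
  spec <- ph$spec
  sigMR <- spec@contrast$MR_bSSFP[["body"]] / spec@mrSNR
  sigCPMG <- spec@contrast$MR_CPMG[["body"]] / spec@mrSNR
  # adrenals and tumour invisible in CT, clearly visible in MR
  expect_lt(contrastToNoise(ph$ct, ph$truth, "adrenal_L",
                            spec@ctNoiseSigma), 1)
  expect_lt(contrastToNoise(ph$ct, ph$truth, "tumour", spec@ctNoiseSigma), 1)
  expect_gte(contrastToNoise(ph$bssfp, ph$truthMR, "adrenal_L", sigMR), 5)
  # CPMG gives the best tumour-to-normal-tissue contrast
  cnrT <- c(bssfp = contrastToNoise(ph$bssfp, ph$truthMR, "tumour", sigMR),
            cpmg = contrastToNoise(ph$cpmg, ph$truthMR, "tumour", sigCPMG))
  expect_gt(cnrT[["cpmg"]], cnrT[["bssfp"]])
  # default anatomy sizes: adrenals 1.5-3 mm, tumour 4-5 mm diameter
  dA <- equivalentSphereDiameterMm(ph$truth, "adrenal_L")
  expect_true(dA >= 1.5 && dA <= 3)
  dT <- equivalentSphereDiameterMm(ph$truth, "tumour")
  expect_true(dT >= 4 && dT <= 5)
  # all named organs present
  expect_setequal(structureNames(ph$truth),
                  c("body", "liver", "stomach", "bowel", "spleen",
                    "kidney_L", "kidney_R", "adrenal_L", "adrenal_R",
                    "bladder", "tumour"))
})

test_that("noise-free renderings equal the contrast table exactly", {
  ph <- coarseMouseClean()
  tab <- ph$spec@contrast$MR_bSSFP
  for (nm in c("liver", "kidney_L", "tumour", "bladder"))
    expect_equal(unique(voxels(ph$bssfpClean)[structureMask(ph$truthMR, nm)]),
                 tab[[nm]])
})

test_that("overlapping organs are rejected with the colliding pair named", {
  og <- murt:::.defaultOrgans(4.8)
  og$tumour$centre <- og$kidney_R$centre + c(0.5, 0, 0)
  expect_error(makeMousePhantom(mousePhantomSpec(ctSpacingMm = 0.6,
                                                 mrSpacingMm = 0.6,
                                                 organs = og)),
               "tumour and kidney_R")
})

test_that("Rician organ means are unbiased after background correction", {
  ph <- coarseMouse()
  spec <- ph$spec
  sig <- spec@contrast$MR_bSSFP[["body"]] / spec@mrSNR
  for (nm in c("liver", "kidney_L", "bladder")) {
    m <- structureMask(ph$truthMR, nm)
    est <- riceCorrectedMean(mean(voxels(ph$bssfp)[m]^2), sig)
    expect_lt(abs(est / spec@contrast$MR_bSSFP[[nm]] - 1), 0.02)
  }
})

test_that("motion models apply the exact field they report", {
  ph <- coarseMouseClean()
  # zero spec: bit identical
  z <- applyMotion(ph$bssfpClean, motionSpec(), "intrinsic",
                   truth = ph$truthMR)
  expect_identical(voxels(z$result), voxels(ph$bssfpClean))
  expect_true(all(z$field@displacements == 0))
  zd <- applyMotion(ph$bssfpClean, motionSpec(), "mr_distortion")
  expect_identical(voxels(zd$result), voxels(ph$bssfpClean))

  # droop: zero at the cradle contact line, full amplitude at the far surface
  mo <- motionSpec(droopAmplitudeMm = 1, seed = 2)
  dr <- applyMotion(ph$bssfpClean, mo, "intrinsic", truth = ph$truthMR)
  u <- dr$field@displacements
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  body <- structureMask(ph$truthMR, "body")
  W <- worldGrid(ph$bssfpClean)
  expect_equal(max(mag[body]), 1, tolerance = 1e-6)
  expect_equal(W$y[body][which.max(mag[body])], max(W$y[body]))
  contact <- body & W$y < min(W$y[body]) + 0.51
  expect_lt(max(mag[contact]), 0.05)

  # mr_distortion scales to the requested peak amplitude
  md <- applyMotion(ph$bssfpClean, motionSpec(distortionAmplitudeMm = 1.5,
                                              seed = 6), "mr_distortion")
  um <- md$field@displacements
  expect_equal(max(sqrt(um[, , , 1]^2 + um[, , , 2]^2 + um[, , , 3]^2)), 1.5,
               tolerance = 1e-6)
  expect_error(motionSpec(droopAmplitudeMm = -1), "amplitudes")
})

test_that("virtual gel readout responds monotonically above threshold", {
  ph <- coarseGel()
  mr <- ph$mrClean
  zero <- asDoseGrid(array(0, dim(voxels(mr))), mr)
  expect_identical(voxels(gelMRAfterDose(mr, zero)), voxels(mr))
  neg <- zero
  neg@voxels[1] <- -0.5
  expect_error(gelMRAfterDose(mr, neg), "negative")
  # monotone response over 0-10 Gy
  resp <- gelResponse()
  d <- seq(0, 10, by = 0.25)
  s <- resp$sMax * (1 - exp(-resp$k * pmax(d - resp$visibilityGy, 0)))
  expect_true(all(diff(s) >= 0))
  # the 2/2/4 Gy cross-beam pattern yields three separable classes
  target <- c(3, 10, -2)
  bA <- beamSpec("static", isocentreMm = target, collimatorMm = 2,
                 gantryDeg = 90)
  bB <- beamSpec("static", isocentreMm = target, collimatorMm = 2,
                 direction = c(0, 0, -1))
  cr <- composeCrossBeams(ph$ctClean, bA, bB, 2, grid = ph$mrClean)
  gelMask <- structureMask(ph$truthMR, "gel")
  post <- gelMRAfterDose(ph$mrClean, cr$dose, gelMask = gelMask)
  post <- addImageNoise(post, "rician", 400 / 20, seed = 9)
  # segment the intersection at the 3 Gy mid-level between the path and
  # intersection plateaus, via the inverse response curve
  resp <- gelResponse()
  fD <- function(D) resp$sMax * (1 - exp(-resp$k * pmax(D - 1, 0)))
  thr <- 400 + fD(3)
  rec <- voxels(post) > thr & gelMask
  truthMask <- voxels(cr$dose) > 3 & gelMask
  expect_gte(diceCoefficient(rec, truthMask), 0.9)
})
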