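test_that("isocentre definition finds centroids and models operator jitter", {
  ref <- imageVolume(array(0, c(40, 40, 40)), spacing = rep(0.5, 3),
                     origin = rep(-10, 3) + 0.25)
  W <- worldGrid(ref)
  mask <- (W$x - 2)^2 + (W$y + 1)^2 + (W$z - 3)^2 < 4^2
  expect_equal(defineIsocentre(mask, ref), c(2, -1, 3), tolerance = 1e-6)
  expect_error(defineIsocentre(array(FALSE, c(4, 4, 4)), ref), "empty")
  # jittered centres follow the 3D Gaussian radial (Maxwell) mean
  set.seed(12)
  off <- replicate(200, sqrt(sum((defineIsocentre(mask, ref,
                                                  jitterSigmaMm = 0.25) -
                                  c(2, -1, 3))^2)))
  expect_lt(abs(mean(off) / (2 * 0.25 * sqrt(2 / pi)) - 1), 0.1)
})

test_that("the cross-beam intersection centroid marks the crossing point", {
  ct <- waterCylinder()
  iso <- c(2, -1, 1)
  bA <- beamSpec("static", isocentreMm = iso, collimatorMm = 2,
                 gantryDeg = 90)
  bB <- beamSpec("static", isocentreMm = iso, collimatorMm = 2,
                 direction = c(0, 0, -1))
  cr <- composeCrossBeams(ct, bA, bB, 2)
  c0 <- defineIsocentre(cr$intersectionMask, cr$dose)
  expect_lt(sqrt(sum((c0 - iso)^2)), 0.5 * 0.4)
})

test_that("collimator choice matches the target's beam's-eye-view extent", {
  ref <- imageVolume(array(0, c(60, 60, 60)), spacing = rep(0.4, 3),
                     origin = rep(-12, 3) + 0.2)
  W <- worldGrid(ref)
  sphereMask <- function(d) W$x^2 + W$y^2 + W$z^2 < (d / 2)^2
  expect_equal(chooseCollimator(sphereMask(2.4), gridObj = ref), 3)
  expect_equal(chooseCollimator(sphereMask(4.8), gridObj = ref), 5)
  expect_warning(col <- chooseCollimator(sphereMask(12), gridObj = ref),
                 "more than one field")
  expect_equal(col, 10)
  # the adrenal-sized default picks 2 or 3 mm
  ph <- coarseMouse()
  expect_true(chooseCollimator(ph$truthMR, name = "adrenal_L") %in% c(2, 3))
})

test_that("the four comparison plans have the prescribed geometries", {
  plans <- makeComparisonPlans(c(4.5, 2, 4), 10, 8)
  expect_named(plans, c("arc45", "beam0", "arc3060", "gantry2x120"))
  kinds <- lapply(plans, function(p) vapply(p@beams, function(b) b@kind, ""))
  expect_equal(kinds$arc45, "conical_arc")
  expect_equal(kinds$beam0, "static")
  expect_equal(kinds$arc3060, c("conical_arc", "conical_arc"))
  expect_equal(kinds$gantry2x120, c("gantry_arc", "gantry_arc"))
  expect_equal(plans$arc45@beams[[1]]@gantryDeg, 45)
  expect_equal(vapply(plans$arc3060@beams, function(b) b@gantryDeg, 1),
               c(30, 60))
  # the static beam is vertical through the isocentre
  expect_equal(murt:::.beamDirection(plans$beam0@beams[[1]]), c(0, -1, 0))
  # total gantry travel of the double arc is 240 degrees
  expect_equal(sum(vapply(plans$gantry2x120@beams,
                          function(b) abs(diff(b@sweepDeg)), 1)), 240)
})

test_that("cumulative DVHs are exact on piecewise-constant doses", {
  lab <- array(0L, c(20, 20, 20))
  lab[3:18, 3:18, 3:10] <- 1L   # one structure, two dose compartments
  ss <- structureSet(lab, diag(4), c(target = 1))
  dose <- array(0, c(20, 20, 20))
  dose[, , 3:6] <- 2; dose[, , 7:10] <- 6
  dg <- imageVolume(dose, affine = diag(4), modality = "DOSE")
  dvh <- computeDVH(dg, ss, binWidthGy = 0.1)
  expect_equal(dvhAt(dvh, "target", 0), 100)
  expect_equal(dvhAt(dvh, "target", 4), 50)
  expect_equal(dvhAt(dvh, "target", 1.95), 100)
  expect_equal(dvhAt(dvh, "target", 6.05), 0)
  expect_true(all(diff(dvh@volumePct["target", ]) <= 1e-9))
  # uniform 4 Gy: a clean step at 4 Gy
  dose4 <- array(0, c(20, 20, 20)); dose4[lab == 1L] <- 4
  dvh4 <- computeDVH(imageVolume(dose4, affine = diag(4),
                                 modality = "DOSE"), ss)
  expect_equal(dvhAt(dvh4, "target", 3.9), 100)
  expect_equal(dvhAt(dvh4, "target", 4.05), 0)
  expect_error(computeDVH(dg, structureSet(lab[1:10, , ], diag(4),
                                           c(target = 1))), "grid")
})

# --- synthetic gel readout pair, built without the dose engine, for
# targeted evaluateTargeting checks ------------------------------------------
syntheticReadout <- function(deltaMm = c(0, 0, 0), seed = 1,
                             spacing = 0.4) {
  n <- round(c(30, 30, 30) / spacing)
  ref <- imageVolume(array(0, n), spacing = rep(spacing, 3),
                     origin = -c(15, 15, 15) + spacing / 2,
                     modality = "MR_CEFAST")
  W <- worldGrid(ref)
  gel <- W$x^2 + W$z^2 < 12^2 & abs(W$y) < 12
  p0 <- c(2, 1, -1.5)
  cylA <- (W$y - p0[2])^2 + (W$z - p0[3])^2 < 1 & gel
  cylB <- (W$x - p0[1])^2 + (W$y - p0[2])^2 < 1 & gel
  D1 <- 2 * cylA + 2 * cylB
  resp <- gelResponse()
  f <- function(D) resp$sMax * (1 - exp(-resp$k * pmax(D - resp$visibilityGy,
                                                       0)))
  pre <- array(0, n); pre[gel] <- 400
  pre <- pre + f(D1) * gel
  p1 <- p0 + deltaMm
  ball <- sqrt((W$x - p1[1])^2 + (W$y - p1[2])^2 + (W$z - p1[3])^2)
  D2 <- 4 * pmin(pmax((2.5 - ball) / 0.3, 0), 1)   # 5 mm plateau, soft edge
  post <- pre + (f(D1 + D2) - f(D1)) * gel
  mk <- function(a) addImageNoise(imageVolume(a, affine = imageAffine(ref),
                                              modality = "MR_CEFAST"),
                                  "rician", 20, seed = seed)
  list(pre = mk(pre), post = mk(post + 0), gel = gel, truthOffset =
         sqrt(sum(deltaMm^2)))
}

test_that("targeting evaluation reports injected offsets faithfully", {
  # zero offset, no jitter: sub-voxel self-consistency
  s0 <- syntheticReadout(c(0, 0, 0), seed = 3)
  ev0 <- evaluateTargeting(s0$pre, s0$post, gelMask = s0$gel)
  expect_lt(ev0$offsetVoxels, 0.5)
  # deliberate 1.0 mm misdelivery is reported as 1.0 +/- 0.1 mm
  s1 <- syntheticReadout(c(0.6, -0.64, 0.48), seed = 4)
  ev1 <- evaluateTargeting(s1$pre, s1$post, gelMask = s1$gel)
  expect_lt(abs(ev1$offsetMm - 1.0), 0.1)
  # automatic gel mask works too
  ev1b <- evaluateTargeting(s1$pre, s1$post)
  expect_lt(abs(ev1b$offsetMm - ev1$offsetMm), 0.1)
  expect_error(evaluateTargeting(s1$pre, imageVolume(voxels(s1$pre),
                                                     affine = diag(4),
                                                     modality = "MR_CEFAST")),
               "grid")
})

test_that("a missing high-dose region is a readout error", {
  s <- syntheticReadout(c(0, 0, 0), seed = 9)
  expect_error(evaluateTargeting(s$pre, s$pre, gelMask = s$gel),
               "readout error")
})

test_that("targeting evaluation is unbiased over repeated zero-jitter runs", {
  offs <- vapply(1:20, function(s) {
    sr <- syntheticReadout(c(0, 0, 0), seed = 100 + s)
    evaluateTargeting(sr$pre, sr$post, gelMask = sr$gel)$offsetVoxels
  }, 1)
  expect_lt(mean(offs), 0.2)
})
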