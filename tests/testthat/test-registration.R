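test_that("region growing segments the gel and rejects bad seeds", {
  ph <- coarseGel()
  seg <- segmentRegionGrowing(ph$ct, c(0, 5, 0), c(850, 1150), "gel")
  expect_gte(diceCoefficient(seg@labels == 1, structureMask(ph$truth, "gel")),
             0.98)
  # glass vial excluded by the window
  expect_equal(sum(seg@labels == 1 & structureMask(ph$truth, "vial")), 0)
  # uniform volume, all-inclusive window: the whole volume
  u <- imageVolume(array(5, c(10, 10, 10)), spacing = c(1, 1, 1))
  expect_equal(sum(segmentRegionGrowing(u, c(4, 4, 4), c(0, 10))@labels), 1000)
  # background seed with a gel-only window: seed error
  expect_error(segmentRegionGrowing(ph$ct, c(-15, 25, -15), c(850, 1150)),
               "seed")
})

test_that("surface point clouds sit on the boundary at the right density", {
  # voxelized sphere r = 5 mm
  ref <- imageVolume(array(0, c(36, 36, 36)), spacing = rep(0.5, 3),
                     origin = rep(-9, 3) + 0.25)
  W <- worldGrid(ref)
  mask <- W$x^2 + W$y^2 + W$z^2 < 25
  pc <- maskToSurfacePoints(mask, 0.5, affine = imageAffine(ref))
  r <- sqrt(rowSums(pc@points^2))
  expect_lte(mean(abs(r - 5)), 0.5)
  expect_lt(abs(nrow(pc@points) / (4 * pi * 25 / 0.25) - 1), 0.25)
  expect_equal(nrow(pc@normals), nrow(pc@points))
  # normals point radially outward for a sphere
  aligned <- rowSums(pc@normals * pc@points / r)
  expect_gt(mean(aligned), 0.9)
  # single-voxel mask: points at that voxel
  m1 <- array(FALSE, c(9, 9, 9)); m1[5, 5, 5] <- TRUE
  p1 <- maskToSurfacePoints(m1, 0.2, affine = diag(4))
  expect_true(all(sqrt(rowSums(sweep(p1@points, 2, c(4, 4, 4))^2)) < 1))
  expect_error(maskToSurfacePoints(array(FALSE, c(4, 4, 4)), 1,
                                   affine = diag(4)), "empty")
  # gel surface count within 25% of area / spacing^2
  ph <- coarseGel()
  pg <- maskToSurfacePoints(ph$truth, 1, name = "gel")
  sp <- ph$spec
  ri <- sp@vialInnerDiameterMm / 2
  area <- 2 * pi * ri * sp@gelHeightMm + 2 * pi * ri^2 / cos(15 * pi / 180)
  expect_lt(abs(nrow(pg@points) / area - 1), 0.25)
})

test_that("ICP recovers applied rigid transforms, also with outliers", {
  ph <- coarseGel()
  pc <- maskToSurfacePoints(ph$truth, 1.2, name = "gel")
  tp <- rbind(c(3, 10, -2), c(0, 0, 0), c(-8, 15, 5))
  tt <- rigidTransform(anglesDeg = c(0, 10, 0), translation = c(1, 2, 3))
  pm <- pointCloud(applyRigid(invertRigid(tt), pc@points))
  reg <- icpRegister(pm, pc)
  expect_lt(transformDiscrepancyMm(reg$transform, tt, tp), 0.1)
  expect_lt(rotationAngleDeg(composeRigid(invertRigid(tt), reg$transform)),
            0.2)
  expect_lt(reg$rmsMm, 0.05)
  # identity in, identity out
  r0 <- icpRegister(pc, pc)
  expect_lt(transformDiscrepancyMm(r0$transform, rigidTransform(), tp), 1e-6)
  expect_lt(r0$rmsMm, 1e-9)
  # 20% gross outliers, trimmed fit
  set.seed(7)
  nOut <- round(0.2 * nrow(pc@points))
  out <- matrix(runif(3 * nOut, -20, 20), ncol = 3)
  pmo <- pointCloud(rbind(applyRigid(invertRigid(tt), pc@points), out))
  rego <- icpRegister(pmo, pc, trim = 0.25)
  expect_lt(transformDiscrepancyMm(rego$transform, tt, tp), 0.3)
  expect_lt(rotationAngleDeg(composeRigid(invertRigid(tt), rego$transform)),
            0.5)
})

test_that("nearly collinear geometry raises a rank warning", {
  line <- cbind(seq(0, 10, length.out = 50), rnorm(50, sd = 1e-4),
                rnorm(50, sd = 1e-4))
  pc <- pointCloud(line)
  expect_warning(icpRegister(pc, pc, method = "point_to_point",
                             maxIter = 1), "collinear")
})

test_that("ICP A->B and B->A are mutually inverse on rigid cases", {
  ph <- coarseGel()
  pc <- maskToSurfacePoints(ph$truth, 1.2, name = "gel")
  set.seed(31)
  tt <- randomRigid(5, 3)
  pm <- pointCloud(applyRigid(tt, pc@points),
                   pc@normals %*% t(tt@rotation))
  ab <- icpRegister(pm, pc)$transform
  ba <- icpRegister(pc, pm)$transform
  tp <- rbind(c(3, 10, -2), c(0, 18, 0), c(-10, 0, 10))
  expect_lt(transformDiscrepancyMm(composeRigid(ab, ba), rigidTransform(),
                                   tp), 0.2)
})

test_that("rigid MI registration recovers shifts and cross-modality poses", {
  ph <- coarseMouseClean()
  p <- rbind(c(4.5, 2, 4), c(-5, -3, -1), c(0, 0, 10))
  # same modality, pure 1.7 mm shift
  tr <- rigidTransform(translation = c(1.7, 0, 0))
  mov <- resample(ph$bssfpClean, invertRigid(tr), ph$bssfpClean)
  rec <- rigidRegisterIntensity(mov, ph$bssfpClean)
  expect_lt(transformDiscrepancyMm(rec, tr, p), 0.1)
  # identical inputs: identity
  r0 <- rigidRegisterIntensity(ph$bssfpClean, ph$bssfpClean)
  expect_lt(transformDiscrepancyMm(r0, rigidTransform(), p), 0.1)
  # cross modality: MR in a different pose vs the CT rendering
  set.seed(5)
  pose <- randomRigid(3, 1.5)
  ph2 <- makeMousePhantom(coarseMouseSpec(), pose = pose, noise = FALSE)
  rec2 <- rigidRegisterIntensity(ph2$bssfpClean, ph2$ctClean, metric = "MI")
  tru <- invertRigid(pose)
  expect_lt(transformDiscrepancyMm(rec2, tru, p), 0.3)
  expect_lt(rotationAngleDeg(composeRigid(invertRigid(tru), rec2)), 0.5)
  # non-overlapping fields of view refuse to start
  far <- imageVolume(voxels(ph$bssfpClean),
                     affine = {
                       A <- imageAffine(ph$bssfpClean); A[1, 4] <- 500; A
                     }, modality = "MR_bSSFP")
  expect_error(rigidRegisterIntensity(far, ph$bssfpClean), "overlap")
})

test_that("extrinsic pose jitter is recovered by rigid registration", {
  spec <- mousePhantomSpec(ctSpacingMm = 0.3, mrSpacingMm = 0.3)
  ph0 <- makeMousePhantom(spec, noise = FALSE)
  set.seed(3)
  tr <- randomRigid(2, 0.5)
  tr@translation <- tr@translation / sqrt(sum(tr@translation^2)) * 0.5
  ph1 <- makeMousePhantom(spec, pose = tr, noise = FALSE)
  rec <- rigidRegisterIntensity(ph0$bssfpClean, ph1$bssfpClean)
  pts <- rbind(c(0, 0, 0), c(5, -3, 1), c(-5, 2, 8), c(0, 4, -10))
  expect_lt(transformDiscrepancyMm(rec, tr, pts), 0.1)
  expect_lt(rotationAngleDeg(composeRigid(invertRigid(tr), rec)), 0.2)
})

test_that("MIND descriptors are contrast-agnostic and edge-sensitive", {
  ph <- coarseMouseClean()
  v <- downsampleVolume(ph$bssfpClean, 2)
  md <- mindDescriptor(v)
  expect_gt(min(md@descriptors), 0)
  expect_lte(max(md@descriptors), 1)
  expect_equal(apply(md@descriptors, 1, max), rep(1, nrow(md@descriptors)))
  # invariance under affine intensity maps, including inversion
  vA <- imageVolume(3.5 * voxels(v) + 120, affine = imageAffine(v),
                    modality = "MR_bSSFP")
  expect_lt(max(abs(mindDescriptor(vA)@descriptors - md@descriptors)), 1e-6)
  vI <- imageVolume(-voxels(v) + 1000, affine = imageAffine(v),
                    modality = "MR_bSSFP")
  expect_lt(max(abs(mindDescriptor(vI)@descriptors - md@descriptors)), 1e-6)
  # constant image: variance floor keeps descriptors defined
  cst <- imageVolume(array(7, c(12, 12, 12)), spacing = c(1, 1, 1))
  expect_true(all(is.finite(mindDescriptor(cst)@descriptors)))

  # step edge: descriptor change across the edge dwarfs flat-region change
  arr <- array(0, c(24, 24, 24)); arr[13:24, , ] <- 100
  se <- imageVolume(arr, spacing = c(1, 1, 1))
  ds <- mindDescriptor(se)@descriptors
  d3 <- array(ds, c(24, 24, 24, 6))
  across <- sqrt(sum((d3[12, 12, 12, ] - d3[13, 12, 12, ])^2))
  flat <- sqrt(sum((d3[5, 12, 12, ] - d3[6, 12, 12, ])^2))
  expect_gt(across / max(flat, 1e-12), 5)

  # white noise: direction-mean descriptors are uniform within 10%
  set.seed(2)
  wn <- imageVolume(array(rnorm(20^3), c(20, 20, 20)), spacing = c(1, 1, 1))
  dm <- colMeans(mindDescriptor(wn)@descriptors)
  expect_lt((max(dm) - min(dm)) / mean(dm), 0.1)
})

test_that("MIND deformable registration undoes a known smooth distortion", {
  spec <- mousePhantomSpec(ctSpacingMm = 0.7, mrSpacingMm = 0.7)
  ph <- makeMousePhantom(spec, noise = FALSE)
  ctOnMR <- resample(ph$ctClean, NULL, ph$bssfpClean)
  # moving == fixed: negligible field
  reg0 <- deformableRegisterMind(ctOnMR, ctOnMR, levels = 2,
                                 iterations = c(10, 5))
  expect_lt(max(abs(reg0$field@displacements)) / 0.7, 0.05)
  # cross-modality recovery of a 1.5 mm polynomial warp
  mo <- motionSpec(distortionAmplitudeMm = 1.5, seed = 7)
  dist <- applyMotion(ph$bssfpClean, mo, "mr_distortion")
  reg <- deformableRegisterMind(dist$result, ctOnMR, levels = 3)
  inv <- invertDeformationField(dist$field)
  err <- sqrt(apply((reg$field@displacements - inv@displacements)^2, 1:3,
                    sum))
  body <- structureMask(ph$truthMR, "body")
  expect_lt(mean(err[body]), 0.35)
  # the deformable step strictly reduces descriptor SSD vs rigid-only
  expect_lt(mindSSD(resample(dist$result, reg$field, ctOnMR), ctOnMR),
            mindSSD(resample(dist$result, NULL, ctOnMR), ctOnMR))
})

test_that("registration chain transfers to a co-acquired contrast", {
  spec <- mousePhantomSpec(ctSpacingMm = 0.5, mrSpacingMm = 0.5)
  set.seed(11)
  pose <- randomRigid(3, 2)
  ph <- makeMousePhantom(spec, pose = pose, noise = FALSE)
  chain <- list(rigid = rigidRegisterIntensity(ph$bssfpClean, ph$ctClean))
  # same volume through the chain equals the directly registered result
  outB <- transferTransform(chain, ph$bssfpClean, ph$ctClean)
  direct <- resample(ph$bssfpClean, chain$rigid, ph$ctClean)
  expect_lt(max(abs(voxels(outB) - voxels(direct))), 1e-9)
  # CPMG rides along: tumour centroid lands within 0.3 mm of truth
  outC <- transferTransform(chain, ph$cpmgClean, ph$ctClean)
  tum <- voxels(outC) > 700
  expect_gt(sum(tum), 0)
  cT <- maskCentroid(tum, outC)
  cTrue <- maskCentroid(structureMask(ph$truth, "tumour"), ph$truth)
  expect_lt(sqrt(sum((cT - cTrue)^2)), 0.3)
  expect_equal(outC@frame, ph$ctClean@frame)
  # declared frame mismatch is refused
  expect_error(transferTransform(chain, ph$cpmgClean, ph$ctClean,
                                 primaryFrame = "other"), "frame mismatch")
  # round trip CT grid -> MR grid -> CT grid stays within 2% of range
  ctOnMR <- resample(ph$ctClean, NULL, ph$bssfpClean)
  back <- resample(ctOnMR, NULL, ph$ctClean)
  core <- structureMask(ph$truth, "body")
  # erode the comparison to smooth regions away from boundaries
  core <- core & voxels(ph$ctClean) >= 1000
  dr <- diff(range(voxels(ph$ctClean)))
  expect_lt(max(abs((voxels(back) - voxels(ph$ctClean))[core])) / dr, 0.02)
})
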