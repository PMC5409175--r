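test_that("central-axis depth dose follows attenuation and inverse square", {
  ct <- waterCylinder()
  b <- beamSpec("static", isocentreMm = c(0, 0, 0), collimatorMm = 5)
  dg <- traceStaticBeam(ct, b, doseEngine(stepMm = 0.05))
  depths <- seq(-8, 8, by = 2)  # along the axis; entry surface at y = 15
  dax <- sampleAtWorld(dg, cbind(0, depths, 0))
  pred <- exp(-0.02 * (15 - depths)) * (350 / (350 - depths))^2
  expect_lt(max(abs((dax / dax[1]) / (pred / pred[1]) - 1)), 0.01)
  # dose decreases monotonically with depth beyond the surface
  prof <- sampleAtWorld(dg, cbind(0, seq(14, -14, by = -0.5), 0))
  expect_true(all(diff(prof) < 0))
})

test_that("an unattenuated beam at large SAD has a flat axis profile", {
  air <- imageVolume(array(0, c(60, 60, 60)), spacing = rep(0.4, 3),
                     origin = rep(-12, 3) + 0.2)
  b <- beamSpec("static", isocentreMm = c(0, 0, 0), collimatorMm = 5,
                sadMm = 5000)
  dg <- traceStaticBeam(air, b, doseEngine(stepMm = 0.2))
  da <- sampleAtWorld(dg, cbind(0, seq(-10, 10, by = 2), 0))
  expect_lt(max(abs(da / mean(da) - 1)), 0.005)
})

test_that("the 20-80% penumbra width equals 1.683 sigma", {
  ct <- waterCylinder(n = c(120, 40, 120), spacing = 0.1, radius = 5,
                      halfHeight = 0.9)
  b <- beamSpec("static", isocentreMm = c(0, 0, 0), collimatorMm = 2)
  dg <- traceStaticBeam(ct, b, doseEngine(stepMm = 0.1))
  x <- seq(0, 3, by = 0.01)
  prof <- sampleAtWorld(dg, cbind(x, 0, 0))
  profn <- prof / prof[1]
  crossing <- function(level) {
    i <- which(profn < level)[1]
    approx(profn[(i - 1):i], x[(i - 1):i], level)$y
  }
  w <- crossing(0.2) - crossing(0.8)
  expect_lt(abs(w / (0.3 * 1.683) - 1), 0.1)
})

test_that("orthogonal cross-beams deliver twice the single-beam dose", {
  ct <- waterCylinder()
  iso <- c(2, -1, 1)
  bA <- beamSpec("static", isocentreMm = iso, collimatorMm = 2,
                 gantryDeg = 90)
  bB <- beamSpec("static", isocentreMm = iso, collimatorMm = 2,
                 direction = c(0, 0, -1))
  cr <- composeCrossBeams(ct, bA, bB, 2)
  expect_lt(abs(sampleAtWorld(cr$dose, iso) / 4 - 1), 0.02)
  expect_true(cr$intersectionMask[
    matrix(round(worldToVoxel(cr$dose, iso)), 1)])
  # weight-zero beam leaves an empty intersection
  bB0 <- beamSpec("static", isocentreMm = iso, collimatorMm = 2,
                  direction = c(0, 0, -1), weight = 0)
  expect_equal(sum(composeCrossBeams(ct, bA, bB0, 2)$intersectionMask), 0)
  # non-orthogonal axes are a geometry error
  bC <- beamSpec("static", isocentreMm = iso, collimatorMm = 2,
                 gantryDeg = 5)
  expect_error(composeCrossBeams(ct, bC, bA, 2), "orthogonal")
})

test_that("the voxelized sharp-edge intersection is a Steinmetz solid", {
  # no penumbra (tiny sigma), no attenuation (air): two orthogonal 2 mm
  # cylinders intersect in 16 r^3 / 3 = 5.33 mm^3
  air <- imageVolume(array(0, c(60, 60, 60)), spacing = rep(0.1, 3),
                     origin = rep(-3, 3) + 0.05)
  iso <- c(0, 0, 0)
  bA <- beamSpec("static", isocentreMm = iso, collimatorMm = 2,
                 gantryDeg = 90, sadMm = 5000)
  bB <- beamSpec("static", isocentreMm = iso, collimatorMm = 2,
                 direction = c(0, 0, -1), sadMm = 5000)
  cr <- composeCrossBeams(air, bA, bB, 2,
                          engine = doseEngine(penumbraSigmaMm = 0.005,
                                              stepMm = 0.2))
  vol <- sum(cr$intersectionMask) * 0.1^3
  expect_lt(abs(vol / steinmetzVolume(2) - 1), 0.05)
})

test_that("nominal target volumes follow the sphere convention", {
  expect_equal(nominalTargetVolume(2), 4 / 3 * pi, tolerance = 1e-12)
  expect_equal(round(nominalTargetVolume(2), 1), 4.2)
  expect_equal(round(nominalTargetVolume(4), 1), 33.5)
  expect_equal(nominalTargetVolume(0), 0)
  expect_equal(steinmetzVolume(2), 16 / 3, tolerance = 1e-12)
})

test_that("arc dose is symmetric, convergent and degenerate-consistent", {
  ct <- waterCylinder(n = c(70, 70, 70), spacing = 0.4, radius = 12,
                      halfHeight = 12)
  beam <- beamSpec("conical_arc", isocentreMm = c(0, 0, 0),
                   collimatorMm = 5, gantryDeg = 45)
  d36 <- arcDose(ct, beam, 36)
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  ring <- sampleAtWorld(d36, cbind(2 * cos(th), 0, 2 * sin(th)))
  expect_lt((max(ring) - min(ring)) / mean(ring), 0.03)
  d72 <- arcDose(ct, beam, 72)
  expect_lt(abs(sampleAtWorld(d72, c(0, 0, 0)) /
                sampleAtWorld(d36, c(0, 0, 0)) - 1), 0.005)
  # a zero-sweep single-control-point gantry arc equals the static beam
  g1 <- beamSpec("gantry_arc", isocentreMm = c(0, 0, 0), collimatorMm = 5,
                 sweepDeg = c(20, 20))
  st <- beamSpec("static", isocentreMm = c(0, 0, 0), collimatorMm = 5,
                 gantryDeg = 20)
  expect_identical(voxels(arcDose(ct, g1, 1)), voxels(traceStaticBeam(ct, st)))
  expect_error(arcDose(ct, g1, 8), "degenerate")
})

test_that("dose respects linearity and collimator monotonicity", {
  ct <- waterCylinder(n = c(50, 50, 50), spacing = 0.5, radius = 10,
                      halfHeight = 10)
  iso <- c(0, 0, 0)
  mk <- function(coll) beamSpec("static", isocentreMm = iso,
                                collimatorMm = coll)
  d2 <- traceStaticBeam(ct, mk(2)); d5 <- traceStaticBeam(ct, mk(5))
  expect_true(all(voxels(d5) - voxels(d2) > -1e-12))
  # superposition is exactly linear
  expect_equal(voxels(d2) + voxels(d5), voxels(d2) + voxels(d5))
  w <- 0.3 * voxels(d2) + 0.7 * voxels(d5)
  expect_equal(max(abs(w - (0.3 * voxels(d2) + 0.7 * voxels(d5)))), 0)
  # beams that miss the volume are a geometry error
  expect_error(traceStaticBeam(ct, beamSpec("static",
                                            isocentreMm = c(100, 0, 0),
                                            collimatorMm = 2)),
               "field of view")
})

test_that("plan normalization hits the prescription at the isocentre", {
  ct <- waterCylinder(n = c(50, 50, 50), spacing = 0.5, radius = 10,
                      halfHeight = 10)
  iso <- c(1, 0.5, -1)
  beam <- beamSpec("static", isocentreMm = iso, collimatorMm = 5)
  plan4 <- treatmentPlan(list(beam), 4)
  d4 <- planDose(ct, plan4)
  expect_lt(abs(sampleAtWorld(d4, iso) / 4 - 1), 0.005)
  plan8 <- treatmentPlan(list(beam), 8)
  d8 <- planDose(ct, plan8)
  expect_equal(voxels(d8), 2 * voxels(d4), tolerance = 1e-9)
  # target_mean on a uniform region matches isocentre normalization there
  raw <- traceStaticBeam(ct, beam)
  m <- array(FALSE, dim(voxels(raw)))
  m[matrix(round(worldToVoxel(raw, iso)), 1)] <- TRUE
  tm <- normalizePlan(raw, treatmentPlan(list(beam), 4,
                                         normalization = "target_mean"),
                      targetMask = m)
  expect_lt(abs(mean(voxels(tm)[m]) / 4 - 1), 1e-9)
  expect_error(normalizePlan(asDoseGrid(array(0, dim(voxels(raw))), raw),
                             plan4), "normalization")
})
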