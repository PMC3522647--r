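test_that("long-T2* phantom has an air capillary, water tube and dipole field", {
  g <- imageGeometry(c(160L, 160L), c(180, 180), 8, "axial")
  ph <- makeLongT2StarPhantom(g)
  expect_true(all(ph@S0[, , 1][ph@truth$capillaryMask] == 0))
  expect_true(all(ph@T2StarMS[, , 1][ph@truth$tubeMask] == 80))
  inObj <- ph@truth$objectMask & !ph@truth$capillaryMask &
    !ph@truth$tubeMask
  expect_true(all(ph@T2StarMS[, , 1][inObj] == 30))
  # perturbation off -> field constant
  ph0 <- makeLongT2StarPhantom(g, perturbAmplitudeHz = 0)
  expect_equal(diff(range(ph0@offResonanceHz)), 0)
  # inverse-square falloff: doubling the distance quarters the field
  f1 <- dipoleFieldHz(2000, 0.25, 4, 0)
  f2 <- dipoleFieldHz(2000, 0.25, 8, 0)
  expect_equal(f2 / f1, 1 / 4, tolerance = 1e-12)
  expect_error(makeLongT2StarPhantom(g, capillaryCenterMM = c(200, 0)),
               "outside")
  expect_error(makeLongT2StarPhantom(g, diameterMM = 400), "fit")
})

test_that("medium-T2* phantom is a uniform 20 ms cylinder", {
  g <- imageGeometry(c(100L, 100L), c(100, 100), 8, "axial")  # 1 mm voxels
  ph <- makeMediumT2StarPhantom(g)
  inObj <- ph@truth$objectMask
  expect_true(all(ph@T2StarMS[, , 1][inObj] == 20))
  # 80 mm diameter spans 80 voxels at 1 mm resolution
  rows <- range(which(apply(inObj, 1, any)))
  expect_equal(diff(rows) + 1, 80, tolerance = 0.03)
  expect_error(makeMediumT2StarPhantom(g, baseT2StarMS = 0), "positive")
})

test_that("heart phantom geometry contracts with a thicker systolic wall", {
  sp <- heartPhantomSpec()
  expect_gt(sp$epiRadiusESMM - sp$endoRadiusESMM,
            sp$epiRadiusEDMM - sp$endoRadiusEDMM)
  hp <- makeHeartPhantom(sp)
  areas <- hp@truth$cavityAreaVox
  expect_gt(max(areas), min(areas))          # contraction happens
  expect_equal(which.max(areas), 1L)         # end-diastole at the trigger
  # incompressible wall: the analytic annulus area is conserved exactly;
  # voxelized counts jitter by boundary discretization only
  wall <- hp@truth$wallAreaVox
  expect_lt(diff(range(wall)) / mean(wall), 0.10)
  sp2 <- hp@truth$spec
  expect_equal(sp2$epiRadiusESMM^2 - sp2$endoRadiusESMM^2,
               sp2$epiRadiusEDMM^2 - sp2$endoRadiusEDMM^2, tolerance = 1e-9)
  expect_error(makeHeartPhantom(heartPhantomSpec(nPhases = 1L)))
  expect_error(heartPhantomSpec(segmentT2StarEDMS = rep(-1, 6)))
})

test_that("cycle modulation has its minimum in systole and 27% amplitude", {
  sp <- heartPhantomSpec()  # default amplitude 0.27
  hp <- makeHeartPhantom(sp)
  segT2 <- hp@truth$segmentT2StarMS
  for (k in 1:6) {
    curve <- segT2[, k]
    # the sampled phases straddle the exact systolic minimum, so the
    # discrete max/min sits just below the configured 1.27
    expect_equal(max(curve) / min(curve), 1.27, tolerance = 2e-3)
    # minimum in systole (normalized position near systoleFraction)
    sMin <- hp@truth$phaseNorm[which.min(curve)]
    expect_lt(abs(sMin - sp$systoleFraction), 0.1)
    # maximum attained after the onset of diastole (relaxation complete)
    expect_true(any(curve[hp@truth$phaseNorm > 0.6] == max(curve)))
  }
  # amplitude 0 -> constant over the cycle
  hp0 <- makeHeartPhantom(heartPhantomSpec(modulationAmplitude = 0))
  expect_equal(diff(range(hp0@truth$segmentT2StarMS[, 1])), 0)
})

test_that("heart phantom anchors segment T2* at the reference ED values", {
  hp <- makeHeartPhantom()
  lab <- hp@truth$segmentLabels[, , 1]
  t2 <- hp@T2StarMS[, , 1]
  ed <- heartPhantomSpec()$segmentT2StarEDMS
  for (k in 1:6)
    expect_equal(unique(t2[which(lab == 6L + k)]), ed[k], tolerance = 1e-9)
})

test_that("breath-hold perturbations are seeded and recorded as ground truth", {
  hp <- makeHeartPhantom(cleanHeartSpec(nPhases = 5L),
                         smallGeom(48L))
  # zero magnitudes -> identical copies
  same <- perturbBreathHolds(hp, 2, shiftVox = 0, shearMag = 0, seed = 3)
  expect_equal(same[[1]]@S0, hp@S0)
  expect_equal(same[[2]]@T2StarMS, hp@T2StarMS)
  # fixed seed -> identical transforms across runs
  a <- perturbBreathHolds(hp, 3, seed = 11)
  b <- perturbBreathHolds(hp, 3, seed = 11)
  for (h in 1:3)
    expect_equal(a[[h]]@truth$appliedTransform@t,
                 b[[h]]@truth$appliedTransform@t)
  # a pure shift is recorded exactly as applied
  tf <- affineTransform2D(diag(2), c(2, -1))
  moved <- makeHeartPhantom(hp@truth$spec, geometry(hp), transform = tf)
  expect_equal(transformPoints(tf, cbind(10, 20)), cbind(12, 19))
  # the anatomy really moved by +2 columns, -1 row (x = col, y = row)
  m0 <- hp@truth$myoMask[, , 1]
  m1 <- moved@truth$myoMask[, , 1]
  expect_equal(m1[1:47, 3:48], m0[2:48, 1:46])
})

test_that("generator segment labels agree with segment_analysis labeling", {
  hp <- makeHeartPhantom()
  lab <- trackROI(hp@truth$myoMask, erodeVox = 0L)
  for (p in c(1L, 10L)) {
    truthLab <- hp@truth$segmentLabels[, , p]
    ours <- lab[, , p]
    both <- !is.na(truthLab) & !is.na(ours)
    expect_gt(mean(ours[both] == truthLab[both]), 0.97)
  }
})
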