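test_that("dual-echo phase difference converts to Hz with wrapping", {
  p1 <- matrix(0, 4, 4)
  fm <- computeB0Map(p1, matrix(pi / 2, 4, 4), 2.04, 3.06)
  expect_equal(fieldValues(fm)[1, 1], (pi / 2) / (2 * pi * 1.02e-3),
               tolerance = 1e-9)                       # 245.1 Hz
  expect_equal(fieldValues(computeB0Map(p1, p1, 2.04, 3.06))[1, 1], 0)
  # 600 Hz at dTE = 1.02 ms aliases to 600 - 1/1.02e-3 = -380.4 Hz
  ph2 <- matrix(wrapPhase(2 * pi * 600 * 1.02e-3), 4, 4)
  expect_equal(fieldValues(computeB0Map(p1, ph2, 2.04, 3.06))[1, 1],
               600 - 1000 / 1.02, tolerance = 1e-6)
  expect_error(computeB0Map(p1, p1, 3.06, 3.06), "exceed")
})

test_that("field mapping inverts simulated phase evolution below Nyquist", {
  g <- smallGeom(32L)
  cc <- voxelCoordsMM(g)
  truth <- 1.2 * cc$x - 0.8 * cc$y  # max ~290 Hz, within the +-490 band
  te <- c(2.04, 3.06)
  ph <- lapply(te, function(t) wrapPhase(2 * pi * truth * t / 1000))
  fm <- computeB0Map(ph[[1]], ph[[2]], te[1], te[2], geom = g)
  expect_lt(max(abs(fieldValues(fm) - truth)), 1e-9)
})

test_that("shim fit recovers exact basis fields and never raises ROI RMS", {
  g <- smallGeom(48L)
  cc <- voxelCoordsMM(g)
  roi <- sqrt(cc$x^2 + cc$y^2) <= 60
  mkMap <- function(f) fieldMap(f, dTEms = 1.02, geom = g,
                                unwrapped = TRUE)
  # linear truth, order 1: residual ~ 0
  lin <- fitShim(mkMap(4 * cc$x - 1.5 * cc$y), roi, 1L)
  expect_lt(shimStats(lin)["postPeakToPeakHz"], 1e-9)
  # pure second-order term: coefficient recovered exactly
  sol <- fitShim(mkMap(5 * (cc$x^2 - cc$y^2)), roi, 2L)
  expect_equal(unname(coef(sol)["x2my2"]), 5, tolerance = 1e-9)
  expect_lt(shimStats(sol)["postRMSHz"], 1e-9)
  # constant field: all gradient/curvature coefficients 0
  cst <- fitShim(mkMap(matrix(120, 48, 48)), roi, 2L)
  expect_equal(max(abs(coef(cst)[-1])), 0, tolerance = 1e-9)
  # random smooth fields: least squares cannot increase the ROI RMS
  set.seed(42)
  for (k in 1:5) {
    co <- stats::rnorm(5, 0, c(10, 3, 3, 0.05, 0.05))
    f <- co[1] + co[2] * cc$x + co[3] * cc$y +
      co[4] * cc$x * cc$y + co[5] * (cc$x^2 - cc$y^2) +
      matrix(stats::rnorm(48^2, 0, 5), 48, 48)
    s <- fitShim(mkMap(f), roi, 2L)
    expect_lte(shimStats(s)["postRMSHz"], shimStats(s)["preRMSHz"] + 1e-9)
  }
  expect_error(fitShim(mkMap(matrix(0, 48, 48)),
                       matrix(FALSE, 48, 48)), "empty")
})

test_that("field statistics report range, FWHM and gradients", {
  g <- imageGeometry(c(50L, 50L), c(50, 50), 4)   # 1 mm voxels
  mkMap <- function(f) fieldMap(f, dTEms = 1.02, geom = g,
                                unwrapped = TRUE)
  # constant field
  s0 <- fieldStats(mkMap(matrix(7, 50, 50)), matrix(TRUE, 50, 50))
  expect_equal(unname(s0["peakToPeakHz"]), 0)
  expect_equal(unname(s0["fwhmHz"]), 0)
  # 3 Hz/mm ramp over a 40 mm ROI: peak-to-peak ~120 Hz, mean gradient 3
  cc <- voxelCoordsMM(g)
  ramp <- 3 * cc$x
  roi <- abs(cc$x) <= 20 & abs(cc$y) <= 20
  s1 <- fieldStats(mkMap(ramp), roi)
  expect_equal(unname(s1["peakToPeakHz"]), 117, tolerance = 0.03) # 39 voxel gaps
  expect_equal(unname(s1["meanGradientHzPerMM"]), 3, tolerance = 1e-6)
  # Gaussian-distributed field: FWHM ~ 2.355 sigma
  set.seed(7)
  gs <- matrix(stats::rnorm(50 * 50, 0, 60), 50, 50)
  s2 <- fieldStats(mkMap(gs), matrix(TRUE, 50, 50))
  expect_equal(unname(s2["fwhmHz"]), 2.355 * 60, tolerance = 0.15)
  # single-voxel ROI: gradients undefined but flagged, not an error
  roi1 <- matrix(FALSE, 50, 50); roi1[25, 25] <- TRUE
  s3 <- fieldStats(mkMap(ramp), roi1)
  expect_true(is.na(s3["maxGradientHzPerMM"]))
  expect_false(attr(s3, "gradientDefined"))
})

test_that("dispersion arithmetic matches the reported per-voxel values", {
  expect_equal(dispersionPerVoxel(3, 4), 12)
  expect_equal(dispersionPerVoxel(20, 4), 80)
  expect_equal(fieldSpanToGradient(80, 40), 2)
  expect_error(dispersionPerVoxel(-3, 4))
})

test_that("order-2 shim flattens the heart phantom background field", {
  hp <- makeHeartPhantom()
  ser <- acquire(hp, protocolPreset("MS", nLines = 128L))
  fm <- b0MapFromSeries(ser)
  roi <- hp@truth$myoMask[, , 1] | hp@truth$cavityMask[, , 1]
  sol <- fitShim(fm, roi, 2L)
  s <- shimStats(sol)
  expect_gte(s["prePeakToPeakHz"] / s["postPeakToPeakHz"], 4)
  expect_lte(s["postRMSHz"], s["preRMSHz"])
  shimmed <- applyShim(fm, sol)
  expect_lte(fieldStats(shimmed, roi)["peakToPeakHz"],
             s["prePeakToPeakHz"])
})
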