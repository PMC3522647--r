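test_that("affine estimation is exact for its transform class", {
  pts <- cbind(c(10, 40, 25, 12), c(8, 14, 40, 33))
  # identical pairs: identity
  id <- estimateAffine(landmarkSet(pts, pts))
  expect_equal(id@A, diag(2), tolerance = 1e-12)
  expect_equal(id@t, c(0, 0), tolerance = 1e-12)
  # pure translation
  tr <- estimateAffine(landmarkSet(pts, sweep(pts, 2, c(2, -1), `+`)))
  expect_equal(tr@A, diag(2), tolerance = 1e-12)
  expect_equal(tr@t, c(2, -1), tolerance = 1e-12)
  # known shear recovered from 3 pairs to machine precision
  sh <- matrix(c(1, 0, 0.1, 1), 2, 2)
  p3 <- pts[1:3, ]
  est <- estimateAffine(landmarkSet(p3, t(sh %*% t(p3)) +
                                          matrix(c(3, 2), 3, 2, byrow = TRUE)))
  expect_equal(est@A, sh, tolerance = 1e-12)
  expect_equal(est@t, c(3, 2), tolerance = 1e-12)
  # collinear landmarks: rank error
  col <- cbind(1:4, 2 * (1:4))
  expect_error(estimateAffine(landmarkSet(col, col + 1)), "collinear")
  expect_error(landmarkSet(pts[1:2, ], pts[1:2, ]))
})

test_that("transform restrictions stay in the declared class", {
  pts <- cbind(c(10, 40, 25, 12), c(8, 14, 40, 33))
  dst <- t(matrix(c(1, 0.02, 0.05, 1), 2, 2) %*% t(pts)) +
    matrix(c(1.5, -2), 4, 2, byrow = TRUE)
  tOnly <- estimateAffine(landmarkSet(pts, dst), "translation")
  expect_equal(tOnly@A, diag(2))
  shOnly <- estimateAffine(landmarkSet(pts, dst), "shear")
  expect_equal(diag(shOnly@A), c(1, 1))
  expect_equal(shOnly@A[1, 2], 0.05, tolerance = 1e-9)
})

test_that("image resampling round-trips and rejects singular transforms", {
  set.seed(5)
  img <- matrix(0, 48, 48)
  img[15:34, 18:30] <- 1
  img <- applyTransform(img, affineTransform2D(t = c(0.5, 0.5)))  # soften edges
  # identity returns the input
  expect_equal(applyTransform(img, affineTransform2D()), img)
  # translate +2 then -2: original recovered in the interior
  fwd <- applyTransform(img, affineTransform2D(t = c(2, 0)))
  back <- applyTransform(fwd, affineTransform2D(t = c(-2, 0)))
  interior <- 5:44
  expect_lt(max(abs(back[interior, interior] - img[interior, interior])),
            1e-9)
  expect_error(applyTransform(img, affineTransform2D(matrix(0, 2, 2))))
})

test_that("ground-truth perturbations are recovered below 0.1 voxel", {
  hp <- makeHeartPhantom(cleanHeartSpec(nPhases = 5L), smallGeom(64L))
  holds <- perturbBreathHolds(hp, 3, shiftVox = 2, shearMag = 0.05,
                              seed = 21L)
  refPts <- landmarkRing(64L)
  evalPts <- as.matrix(expand.grid(seq(10, 54, 4), seq(10, 54, 4)))
  for (h in seq_along(holds)) {
    applied <- holds[[h]]@truth$appliedTransform
    est <- estimateAffine(landmarksFromTransform(applied, refPts, h))
    expect_lt(alignmentError(applied, est, evalPts), 0.1)
  }
})

test_that("landmark CSV round-trips through read/write", {
  lms <- list(landmarkSet(cbind(c(1, 5, 9), c(2, 6, 3)),
                          cbind(c(1.5, 5.5, 9.5), c(2, 6, 3)), hold = 1L),
              landmarkSet(cbind(c(11, 15, 19), c(12, 16, 13)),
                          cbind(c(11, 15, 19), c(12.5, 16.5, 13.5)),
                          hold = 2L))
  path <- tempfile(fileext = ".csv")
  writeLandmarks(lms, path)
  back <- readLandmarks(path)
  expect_length(back, 2)
  expect_equal(back[[2]]@src, lms[[2]]@src, ignore_attr = TRUE)
  expect_equal(back[[1]]@dst, lms[[1]]@dst, ignore_attr = TRUE)
})
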