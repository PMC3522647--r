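ringMask <- function(n = 64L, rIn = 10, rOut = 18) {
  ctr <- (n - 1) / 2
  d <- sqrt(outer((0:(n - 1) - ctr)^2, (0:(n - 1) - ctr)^2, `+`))
  d > rIn & d <= rOut
}

test_that("AHA sectors partition the annulus with the standard numbering", {
  m <- ringMask()
  lab <- ahaSegments(m, insertionAngleDeg = 0)
  counts <- table(lab[!is.na(lab)])
  expect_equal(sort(as.integer(names(counts))), 7:12)
  # symmetric annulus: equal voxel counts up to discretization
  expect_lt(diff(range(counts)) / mean(counts), 0.05)
  # labels exist exactly on the mask
  expect_equal(!is.na(lab), m, ignore_attr = TRUE)
  # rotating the insertion angle by 60 degrees permutes labels cyclically
  lab60 <- ahaSegments(m, insertionAngleDeg = 60)
  ok <- !is.na(lab)
  expect_true(all(lab60[ok] == 7L + ((lab[ok] - 7L - 1L) %% 6L)))
  # a voxel 90 degrees from the insertion falls in the second sector
  ctr <- attr(lab, "center")
  # 90 deg counterclockwise from anterior (up) is the -x direction
  vox <- c(round(ctr[2]) + 1, round(ctr[1]) + 1 - 14)  # (row, col+offset)
  expect_equal(lab[vox[1], vox[2]], 8L)
  expect_error(ahaSegments(matrix(FALSE, 8, 8)), "empty")
})

test_that("ROI tracking follows the contracting wall and excludes blood", {
  hp <- makeHeartPhantom(cleanHeartSpec())
  lab <- trackROI(hp@truth$myoMask, erodeVox = 0L)
  # static mask: identical labels at all phases
  st <- array(hp@truth$myoMask[, , 1], dim(hp@truth$myoMask))
  labSt <- trackROI(st, erodeVox = 0L)
  for (p in 2:dim(st)[3])
    expect_identical(labSt[, , p], labSt[, , 1])
  # per-phase sector areas track the generator truth within 5%
  for (p in c(1L, 9L, 17L)) {
    areas <- table(lab[, , p][!is.na(lab[, , p])])
    truthAreas <- hp@truth$segAreaVox[p, ]
    expect_equal(as.numeric(areas), as.numeric(truthAreas),
                 tolerance = 0.05)
  }
  # blood-pool voxels are never labeled (eroded or not)
  labE <- trackROI(hp@truth$myoMask)
  for (p in c(1L, 12L)) {
    expect_true(all(is.na(lab[, , p][hp@truth$cavityMask[, , p]])))
    expect_true(all(is.na(labE[, , p][hp@truth$cavityMask[, , p]])))
  }
  # empty phase flagged, not an error
  m2 <- hp@truth$myoMask
  m2[, , 3] <- FALSE
  expect_equal(attr(trackROI(m2), "emptyPhases"), 3L)
})

test_that("segment statistics recover the configured per-segment T2*", {
  # noiseless acquisition of the frozen end-diastolic frame
  hp <- phantomFrame(makeHeartPhantom(cleanHeartSpec()), 1L)
  ser <- acquire(hp, protocolPreset("MS", nLines = 128L))
  m <- mapFit(ser, hp@truth$myoMask[, , 1] | hp@truth$cavityMask[, , 1])
  lab <- trackROI(hp@truth$myoMask)
  rep <- segmentStats(m, lab)
  sm <- segmentSummary(rep)
  expect_equal(sm$endDiastolicMS, heartPhantomSpec()$segmentT2StarEDMS,
               tolerance = 0.3 / 12)
  # uniform phantom: all segment means equal
  hpU <- phantomFrame(makeHeartPhantom(cleanHeartSpec(
    segmentT2StarEDMS = rep(15, 6), segmentT2StarESMS = rep(12, 6))), 1L)
  serU <- acquire(hpU, protocolPreset("MS", nLines = 128L))
  mU <- mapFit(serU, hpU@truth$myoMask[, , 1])
  repU <- segmentStats(mU, trackROI(hpU@truth$myoMask))
  expect_lt(diff(range(segmentSummary(repU)$endDiastolicMS)), 0.1)
})

test_that("percent increase follows (max - min)/min", {
  # three-phase synthetic map: per-segment series 10, 11, 12.7 -> 27%
  g <- smallGeom(64L)
  m <- ringMask()
  t2 <- array(NA_real_, c(64, 64, 3))
  for (p in 1:3) t2[, , p][m] <- c(10, 11, 12.7)[p]
  map <- new("T2StarMap", t2StarMS = t2, s0 = t2, status = 0L * t2,
             residual = 0 * t2, boundsMS = c(0.1, 200), geometry = g)
  lab <- trackROI(array(m, c(64, 64, 3)), erodeVox = 0L)
  rep <- segmentStats(map, lab, edPhase = 1L, esPhase = 1L)
  expect_equal(segmentSummary(rep)$percentIncrease, rep(27, 6),
               tolerance = 1e-9)
})

test_that("small segments are flagged, not dropped", {
  g <- smallGeom(32L)
  m <- ringMask(32L, 4, 7)
  t2 <- array(NA_real_, c(32, 32, 1))
  t2[, , 1][m] <- 15
  map <- new("T2StarMap", t2StarMS = t2, s0 = t2, status = 0L * t2,
             residual = 0 * t2, boundsMS = c(0.1, 200), geometry = g)
  lab <- trackROI(array(m, c(32, 32, 1)), erodeVox = 0L)
  rep <- segmentStats(map, lab, edPhase = 1L, esPhase = 1L,
                      minVoxels = 100L)
  tab <- reportTable(rep)
  expect_equal(nrow(tab), 6)          # 6 segments x 1 phase, all present
  expect_true(all(tab$flagged))
})

test_that("paired comparison matches its closed form and reference routine", {
  r <- pairedComparison(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  expect_equal(r$p, 0.07417990, tolerance = 1e-6)
  # cross-check against the reference implementation
  set.seed(12)
  x <- stats::rnorm(8, 15, 2); y <- stats::rnorm(8, 13, 2)
  ref <- stats::t.test(x, y, paired = TRUE)
  r2 <- pairedComparison(x, y)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-12)
  # reversing pair order negates t, p unchanged
  r3 <- pairedComparison(y, x)
  expect_equal(r3$t, -r2$t)
  expect_equal(r3$p, r2$p)
  # identical vectors: degenerate, t = 0, p = 1
  r4 <- pairedComparison(c(1, 2, 3), c(1, 2, 3))
  expect_true(r4$degenerate)
  expect_equal(r4$t, 0)
  expect_equal(r4$p, 1)
  expect_error(pairedComparison(1, c(1, 2)))
})
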