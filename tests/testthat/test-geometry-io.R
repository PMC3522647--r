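test_that("geometry invariants hold and defaults match the in vivo protocol", {
  g <- imageGeometry()
  expect_equal(g@matrixSize, c(256L, 224L))
  expect_equal(g@fovMM, c(288, 252))
  expect_equal(resolutionMM(g), c(288, 252) / c(256, 224))  # ~1.1 mm
  expect_error(imageGeometry(c(0L, 224L)))
  expect_error(imageGeometry(fovMM = c(-1, 252)))
  expect_error(imageGeometry(orientation = "coronal"))
})

test_that("image series round-trip through NIfTI + sidecar losslessly", {
  fx <- mediumFixture(n = 32L)
  ser <- acquire(fx$tissue, protocolPreset("MS_CINE", nLines = 32L,
                                           nCardiacPhases = 25L),
                 noiseSigma = 0.02, seed = 3L)
  fi <- frameInfo(ser)
  expect_equal(nrow(fi), 225)                       # 9 echoes x 25 phases
  expect_equal(max(fi$echo), 9L)
  expect_equal(max(fi$phase), 25L)
  # frames indexed correctly: one frame per (echo, phase)
  expect_equal(nrow(unique(fi[, c("echo", "phase")])), 225)

  prefix <- file.path(tempdir(), "series-roundtrip")
  writeEchoSeries(ser, prefix)
  back <- readImageSeries(prefix)
  expect_equal(magnitudeData(back), unclass(magnitudeData(ser)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(phaseData(back), unclass(phaseData(ser)),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(frameInfo(back)$teMS, fi$teMS)
  gb <- geometry(back)
  expect_equal(gb@matrixSize, geometry(ser)@matrixSize)
  expect_equal(resolutionMM(gb), resolutionMM(geometry(ser)),
               tolerance = 1e-6)
  expect_equal(gb@sliceThicknessMM, geometry(ser)@sliceThicknessMM)
  expect_equal(gb@orientation, geometry(ser)@orientation)

  # sidecar listing fewer frames than the stack: consistency error
  sc <- utils::read.csv(paste0(prefix, "_frames.csv"))
  utils::write.csv(sc[sc$echo <= 8, ], paste0(prefix, "_frames.csv"),
                   row.names = FALSE)
  expect_error(readImageSeries(prefix), "consistency")
  # missing sidecar: format error
  file.remove(paste0(prefix, "_frames.csv"))
  expect_error(readImageSeries(prefix), "format")
})

test_that("segment reports serialize one row per (segment, phase)", {
  g <- smallGeom(64L)
  m <- matrix(FALSE, 64, 64)
  ctr <- 31.5
  d <- sqrt(outer((0:63 - ctr)^2, (0:63 - ctr)^2, `+`))
  m <- d > 10 & d <= 18
  nP <- 25L
  t2 <- array(NA_real_, c(64, 64, nP))
  for (p in seq_len(nP)) t2[, , p][m] <- 14 + p / 10
  map <- new("T2StarMap", t2StarMS = t2, s0 = t2, status = 0L * t2,
             residual = 0 * t2, boundsMS = c(0.1, 200), geometry = g)
  rep <- segmentStats(map, trackROI(array(m, c(64, 64, nP)), erodeVox = 0L),
                      edPhase = nP, esPhase = 1L)
  path <- tempfile(fileext = ".csv")
  writeReport(rep, path, seed = 7L)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 6 * nP)                  # 150 rows
  expect_true(all(tab$seed == 7L))

  # single phase: 6 rows
  rep1 <- segmentStats(new("T2StarMap", t2StarMS = t2[, , 1, drop = FALSE],
                           s0 = t2[, , 1, drop = FALSE],
                           status = 0L * t2[, , 1, drop = FALSE],
                           residual = 0 * t2[, , 1, drop = FALSE],
                           boundsMS = c(0.1, 200), geometry = g),
                       trackROI(array(m, c(64, 64, 1)), erodeVox = 0L),
                       edPhase = 1L, esPhase = 1L)
  p1 <- tempfile(fileext = ".csv")
  writeReport(rep1, p1)
  expect_equal(nrow(utils::read.csv(p1)), 6)

  # an empty segment ROI yields a flagged row, never a dropped one
  mHalf <- m; mHalf[1:32, ] <- FALSE                # upper sectors removed
  ctrs <- matrix(rep(c(31.5, 31.5), each = nP), nP, 2)
  repH <- segmentStats(map, trackROI(array(mHalf, c(64, 64, nP)),
                                     centers = ctrs, erodeVox = 0L),
                       edPhase = 1L, esPhase = 2L)
  tabH <- reportTable(repH)
  expect_equal(nrow(tabH), 6 * nP)
  expect_true(any(tabH$nVoxels == 0 & tabH$flagged))
})

test_that("run configs round-trip through YAML", {
  cfg <- runConfig(phantom = list(type = "heart", nPhases = 12L,
                                  modulationAmplitude = 0.27),
                   protocol = list(strategy = "MB_CINE", nLines = 64L),
                   noiseSigma = 0.02, seed = 42L, outDir = "out-x")
  path <- tempfile(fileext = ".yaml")
  writeRunConfig(cfg, path)
  back <- readRunConfig(path)
  expect_equal(back@phantom, cfg@phantom)
  expect_equal(back@protocol, cfg@protocol)
  expect_equal(back@noiseSigma, cfg@noiseSigma)
  expect_equal(back@seed, cfg@seed)
  expect_equal(back@outDir, cfg@outDir)
  expect_error(runConfig(phantom = list(type = "banana")))
})

test_that("the pipeline is deterministic and validates its configuration", {
  base <- list(phantom = list(type = "medium",
                              geometry = list(matrixSize = c(48L, 48L),
                                              fovMM = c(288, 288))),
               protocol = list(strategy = "MS"),
               noiseSigma = 0.02)
  run <- function(dir) {
    cfg <- runConfig(base$phantom, base$protocol, base$noiseSigma,
                     seed = 5L, outDir = dir)
    runPipeline(cfg)
    readBin(file.path(dir, "report.csv"), "raw",
            file.size(file.path(dir, "report.csv")))
  }
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  expect_identical(run(d1), run(d2))           # byte-identical reports
  # seed recorded in the report
  expect_true(all(utils::read.csv(file.path(d1, "report.csv"))$seed == 5L))
  expect_error(runPipeline(runConfig(protocol = list(strategy = "WRONG"))))
})

test_that("MB CINE pipeline registers three breath-hold series", {
  dir <- file.path(tempdir(), "mb-small")
  cfg <- runConfig(phantom = list(type = "heart", nPhases = 8L,
                                  geometry = list(matrixSize = c(64L, 64L))),
                   protocol = list(strategy = "MB_CINE",
                                   nCardiacPhases = 8L),
                   noiseSigma = 0, seed = 2L, outDir = dir)
  res <- runPipeline(cfg)
  # three per-hold series were produced before registration
  raw <- readImageSeries(file.path(dir, "series"))
  expect_equal(sort(unique(frameInfo(raw)$hold)), 1:3)
  expect_length(res$transforms, 3)
  # after registration the merged series carries all 9 echoes per phase
  fi <- frameInfo(res$series)
  expect_equal(sort(unique(fi$echo)), 1:9)
  expect_s4_class(res$report, "SegmentReport")
  # geometry metadata survives every stage unchanged
  g0 <- geometry(res$tissue)
  for (obj in list(res$series, res$t2map)) {
    expect_equal(geometry(obj)@matrixSize, g0@matrixSize)
    expect_equal(resolutionMM(geometry(obj)), resolutionMM(g0))
  }
  expect_true(file.exists(file.path(dir, "pipeline.log")))
})
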