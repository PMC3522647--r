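test_that("echo interleaving assigns echo subsets per excitation", {
  expect_equal(echoInterleaveSchedule(9, 3),
               list(c(1L, 4L, 7L), c(2L, 5L, 8L), c(3L, 6L, 9L)))
  expect_equal(echoInterleaveSchedule(6, 1), list(1:6))
  expect_equal(lengths(echoInterleaveSchedule(9, 9)), rep(1L, 9))
  expect_error(echoInterleaveSchedule(9, 2), "divisible")
})

test_that("scan durations reproduce the printed protocol table", {
  mk <- function(s, vps = NULL) protocolPreset(s, nLines = 240L,
                                               viewsPerSegment = vps)
  expect_equal(unname(scanDuration(mk("ME"))["totalS"]), 25)
  expect_equal(unname(scanDuration(mk("MS"))["totalS"]), 49)
  d <- scanDuration(mk("MB_CINE"))
  expect_equal(unname(d["perHoldS"]), 81)
  expect_equal(unname(d["nHolds"]), 3)
  expect_equal(unname(scanDuration(mk("ME_CINE"))["totalS"]), 121)
  expect_equal(unname(scanDuration(mk("MS_CINE"))["totalS"]), 241)
  # degenerate: whole k-space in one cycle, no preparation
  p <- protocolPreset("ME", nLines = 240L, viewsPerSegment = 240L,
                      prepCycles = 0L)
  expect_equal(unname(scanDuration(p)["totalS"]), 1)
})

test_that("acquisition windows are views per cycle times TR", {
  expect_equal(acquisitionWindow(protocolPreset("ME_CINE")), 38)   # 2 x 19
  expect_equal(acquisitionWindow(protocolPreset("MS_CINE")), 36)   # 1 x 3 x 12
  expect_equal(acquisitionWindow(protocolPreset("MB_CINE")), 36)   # 3 x 12
  expect_equal(acquisitionWindow(protocolPreset("ME")), 205)
  expect_equal(acquisitionWindow(protocolPreset("MS")), 192)
})

test_that("trigger schedule covers the cycle minus the gap", {
  d <- triggerSchedule(60, 25, 100)
  expect_length(d, 25)
  expect_equal(diff(d)[1], 36)
  expect_equal(max(d), 864)          # spans 0-900 ms exclusive
  expect_lt(max(d), 900)
  full <- triggerSchedule(60, 10, 0)
  expect_equal(max(full), 900)       # gap 0: delays span the full cycle
  expect_length(triggerSchedule(60, 1, 100), 1)
  expect_error(triggerSchedule(60, 25, 1000))
  expect_equal(normalizeCyclePosition(450, 60, 100), 0.5)
})

test_that("static phantom: reconstruction equals the direct render for all strategies", {
  fx <- mediumFixture(n = 64L)
  seqFor <- function(p) sequenceParams(teMS = p@teMS, trMS = p@trMS)
  for (s in c("ME", "MS", "MB_CINE", "ME_CINE", "MS_CINE")) {
    p <- protocolPreset(s, nLines = 64L, nCardiacPhases = 5L)
    ser <- acquire(fx$tissue, p)
    fi <- frameInfo(ser)
    dat <- seriesData(ser)
    for (f in c(1L, nrow(fi))) {
      direct <- CardioT2Star:::renderEchoImage(fx$tissue, 1L,
                                               fi$teMS[f], seqFor(p))
      expect_lt(max(Mod(dat[, , f] - direct)), 1e-9)
    }
  }
})

test_that("MB CINE splits echo subsets over three breath-holds", {
  hp <- makeHeartPhantom(cleanHeartSpec(nPhases = 5L), smallGeom(48L))
  p <- protocolPreset("MB_CINE", nLines = 48L, nCardiacPhases = 5L)
  ser <- acquire(hp, p)
  fi <- frameInfo(ser)
  expect_equal(sort(unique(fi$hold)), 1:3)
  for (h in 1:3)
    expect_equal(sort(unique(fi$echo[fi$hold == h])),
                 seq(h, 9L, by = 3L))
  expect_equal(nrow(fi), 3 * 5 * 3)  # echoes/hold x phases x holds
})

test_that("protocol validation rejects inconsistent configurations", {
  expect_error(protocolPreset("XX"))
  expect_error(acquire(mediumFixture(32L)$tissue,
                       protocolPreset("MS", nLines = 64L)), "exceed")
  p <- protocolPreset("MS", nLines = 32L)
  expect_error(acquire(mediumFixture(32L)$tissue, p,
                       seq = sequenceParams(teMS = echoSchedule(2, 1, 9))),
               "match")
})

test_that("end-diastolic triggering is sharper than mid-systolic for equal windows", {
  hp <- makeHeartPhantom(cleanHeartSpec(), smallGeom(96L))
  mkSer <- function(delay) {
    p <- protocolPreset("MS", nLines = 96L, triggerDelayMS = delay)
    acquire(hp, p)
  }
  sharpness <- function(ser) {
    m <- magnitudeData(ser)[, , 1]      # first echo image
    sum(diff(m)^2) + sum(t(diff(t(m)))^2)
  }
  quiescent <- sharpness(mkSer(650))    # diastasis plateau
  systolic <- sharpness(mkSer(200))     # acquisition through contraction
  expect_gt(quiescent, systolic)
})
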