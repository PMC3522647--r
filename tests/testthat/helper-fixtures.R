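# Shared fixtures, built in code at test time.

smallGeom <- function(n = 64L, fov = 288, thk = 4,
                      orientation = "short-axis") {
  imageGeometry(c(n, n), c(fov, fov), thk, orientation)
}

# medium-T2* cylinder on a small grid with a centred circular ROI
mediumFixture <- function(n = 128L, thk = 4) {
  g <- smallGeom(n, 288, thk)
  ph <- makeMediumT2StarPhantom(g)
  cc <- voxelCoordsMM(g)
  list(geom = g, tissue = ph, roi = sqrt(cc$x^2 + cc$y^2) <= 30)
}

# heart phantom without the macroscopic field-gradient terms: the fixture
# for parameter-recovery experiments, where the configured relaxation must
# be identifiable from the signal
cleanHeartSpec <- function(...) {
  heartPhantomSpec(epicardialGradientHzPerMM = 0, epiDFdzHzPerMM = 0,
                   baseDFdzHzPerMM = 0, backgroundFieldCoef =
                     c(offset = 0, x = 0, y = 0, xy = 0, x2my2 = 0), ...)
}

# landmark ring in voxel coordinates, scaled to the grid
landmarkRing <- function(n) {
  cbind(c(40, 80, 64, 50, 75), c(40, 45, 85, 70, 30)) * n / 128
}

# full MB CINE chain: perturb -> acquire -> register -> fit -> segment
mbCineExperiment <- function(spec, n = 192L, noiseSigma = 0.02, seed = 5L,
                             shiftVox = 2, shearMag = 0.05) {
  g <- imageGeometry(c(n, n), c(288, 288), 4)
  hp <- makeHeartPhantom(spec, g)
  proto <- protocolPreset("MB_CINE", nLines = n)
  holds <- perturbBreathHolds(hp, proto@nBreathHolds, shiftVox = shiftVox,
                              shearMag = shearMag, seed = seed)
  ser <- acquire(holds, proto, noiseSigma = noiseSigma, seed = seed + 1L)
  refPts <- landmarkRing(n)
  lms <- lapply(seq_along(holds), function(h)
    landmarksFromTransform(holds[[h]]@truth$appliedTransform, refPts, h))
  reg <- registerBreathHolds(splitByHold(ser), lms)
  map <- mapFit(reg$series, hp@truth$myoMask | hp@truth$cavityMask)
  labels <- trackROI(hp@truth$myoMask)
  report <- segmentStats(map, labels,
                         cavityAreaVox = hp@truth$cavityAreaVox)
  list(tissue = hp, series = reg$series, map = map, report = report,
       transforms = reg$transforms, holds = holds)
}

# independent oracle for the intravoxel dephasing factor: numeric sum of
# unit phasors over sub-voxel positions with a uniform frequency spread
phasorSumOracle <- function(dispersionHz, teMS, nSub = 1e4) {
  f <- (seq_len(nSub) - 0.5) / nSub - 0.5   # fractions of the spread
  Mod(mean(exp(1i * 2 * pi * (f * dispersionHz) * teMS / 1000)))
}
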