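# Digital phantoms: the two uniform-cylinder physical phantoms (long and
# medium T2*) and a contracting mid-ventricular short-axis heart with
# segment-specific, cyclically modulated T2*, a smooth background B0 field
# and a localized epicardial field gradient. These generators define the
# statistical and physical structure the downstream analysis assumes.

#' Voxel-centre coordinates in mm relative to the image centre
#'
#' @param geom an \linkS4class{ImageGeometry}.
#' @return list with matrices \code{x} (along columns, mm) and \code{y}
#'   (along rows, mm). Row axis runs anterior (top) to inferior (bottom) for
#'   short-axis views, so \code{y} increases toward inferior.
#' @export
voxelCoordsMM <- function(geom) {
  res <- resolutionMM(geom)
  n <- geom@matrixSize
  rowMM <- ((seq_len(n[1]) - 0.5) - n[1] / 2) * res[1]
  colMM <- ((seq_len(n[2]) - 0.5) - n[2] / 2) * res[2]
  list(x = matrix(colMM, n[1], n[2], byrow = TRUE),
       y = matrix(rowMM, n[1], n[2]))
}

# angle in degrees measured counterclockwise (on the displayed image, from
# anterior/up toward the septal side) in [0, 360)
ccwAngleDeg <- function(x, y) {
  (atan2(-x, -y) * 180 / pi + 360) %% 360
}

#' 2D dipole-like field perturbation around a cylindrical inclusion
#'
#' Field offset \code{A (a/r)^2 cos(2 theta)} outside an inclusion of radius
#' \code{a}; the characteristic inverse-square falloff of a susceptibility
#' cylinder perpendicular to the main field. \code{r} is clamped at \code{a}.
#'
#' @param amplitudeHz field offset at the inclusion surface (Hz).
#' @param inclusionRadiusMM inclusion radius a (mm).
#' @param rMM radial distance(s) from the inclusion axis (mm).
#' @param thetaRad azimuthal angle(s) (radians).
#' @return field offset(s) in Hz.
#' @export
dipoleFieldHz <- function(amplitudeHz, inclusionRadiusMM, rMM, thetaRad) {
  r <- pmax(rMM, inclusionRadiusMM)
  amplitudeHz * (inclusionRadiusMM / r)^2 * cos(2 * thetaRad)
}

# ---------------------------------------------------------------------------
# Uniform cylinder phantoms
# ---------------------------------------------------------------------------

#' Long-T2* agarose cylinder phantom with air capillary and water tube
#'
#' A uniform cylinder (default diameter 150 mm, base T2* 30 ms) containing an
#' air-filled glass capillary (inner diameter 0.5 mm, no signal, surrounded
#' by a dipole-like field perturbation) and a water-filled tube (inner
#' diameter 5 mm, long T2*). A uniform through-plane field gradient (default
#' 2 Hz/mm, the post-shim value measured on a uniform phantom) drives
#' slice-thickness-dependent intravoxel dephasing.
#'
#' @param geom \linkS4class{ImageGeometry}; default 320 x 240 over
#'   (360 x 270) mm^2, the phantom-study protocol.
#' @param baseT2StarMS cylinder T2* (ms), default 30.
#' @param diameterMM cylinder diameter, default 150.
#' @param capillaryCenterMM length-2 (x, y) mm position of the air capillary.
#' @param capillaryRadiusMM capillary inner radius, default 0.25.
#' @param tubeCenterMM length-2 (x, y) mm position of the water tube.
#' @param tubeRadiusMM water tube inner radius, default 2.5.
#' @param tubeT2StarMS water tube T2*, default 80 ms.
#' @param perturbAmplitudeHz dipole amplitude at the capillary surface (Hz);
#'   0 switches the perturbation off. Default 2000.
#' @param dFdzHzPerMM uniform through-plane gradient (Hz/mm), default 2.
#' @return a single-phase \linkS4class{TissueMap}.
#' @export
makeLongT2StarPhantom <- function(geom = imageGeometry(c(320L, 240L),
                                                       c(360, 270), 8),
                                  baseT2StarMS = 30, diameterMM = 150,
                                  capillaryCenterMM = c(-30, 0),
                                  capillaryRadiusMM = 0.25,
                                  tubeCenterMM = c(30, 0),
                                  tubeRadiusMM = 2.5, tubeT2StarMS = 80,
                                  perturbAmplitudeHz = 2000,
                                  dFdzHzPerMM = 2) {
  if (baseT2StarMS <= 0 || tubeT2StarMS <= 0)
    stop("T2* must be strictly positive")
  R <- diameterMM / 2
  if (diameterMM > min(geom@fovMM))
    stop("cylinder diameter does not fit in the field of view")
  for (ctr in list(capillaryCenterMM, tubeCenterMM))
    if (sqrt(sum(ctr^2)) >= R)
      stop("inclusion lies outside the cylinder")
  cc <- voxelCoordsMM(geom)
  rCyl <- sqrt(cc$x^2 + cc$y^2)
  inside <- rCyl <= R
  res <- resolutionMM(geom)
  halfVox <- max(res) / 2

  S0 <- ifelse(inside, 1, 0)
  T2 <- matrix(baseT2StarMS, nrow(S0), ncol(S0))
  dxT <- cc$x - tubeCenterMM[1]; dyT <- cc$y - tubeCenterMM[2]
  inTube <- inside & sqrt(dxT^2 + dyT^2) <= tubeRadiusMM
  T2[inTube] <- tubeT2StarMS
  S0[inTube] <- 0.9
  dxC <- cc$x - capillaryCenterMM[1]; dyC <- cc$y - capillaryCenterMM[2]
  rCap <- sqrt(dxC^2 + dyC^2)
  # air capillary: no signal; a sub-voxel capillary still voids the voxel
  # containing its axis
  inCap <- inside & rCap <= max(capillaryRadiusMM, halfVox)
  S0[inCap] <- 0

  df <- matrix(0, nrow(S0), ncol(S0))
  if (perturbAmplitudeHz != 0)
    df <- df + dipoleFieldHz(perturbAmplitudeHz, capillaryRadiusMM, rCap,
                             atan2(dyC, dxC))
  newTissueMap(S0 = S0, T2StarMS = T2, offResonanceHz = df,
               dFdzHzPerMM = matrix(dFdzHzPerMM, nrow(S0), ncol(S0)),
               fatFraction = matrix(0, nrow(S0), ncol(S0)),
               geometry = geom,
               truth = list(objectMask = inside, capillaryMask = inCap,
                            tubeMask = inTube))
}

#' Medium-T2* iron-doped cylinder phantom
#'
#' A uniform cylinder (default diameter 80 mm) with uniform T2* of 20 ms,
#' emulating an agarose solution doped with superparamagnetic iron oxide.
#'
#' @param geom \linkS4class{ImageGeometry}; default as in
#'   \code{\link{makeLongT2StarPhantom}}.
#' @param baseT2StarMS uniform T2* (ms), default 20; must be positive.
#' @param diameterMM cylinder diameter, default 80.
#' @param dFdzHzPerMM uniform through-plane gradient (Hz/mm), default 2.
#' @return a single-phase \linkS4class{TissueMap}.
#' @export
makeMediumT2StarPhantom <- function(geom = imageGeometry(c(320L, 240L),
                                                         c(360, 270), 8),
                                    baseT2StarMS = 20, diameterMM = 80,
                                    dFdzHzPerMM = 2) {
  if (baseT2StarMS <= 0) stop("T2* must be strictly positive")
  if (diameterMM > min(geom@fovMM))
    stop("cylinder diameter does not fit in the field of view")
  cc <- voxelCoordsMM(geom)
  inside <- sqrt(cc$x^2 + cc$y^2) <= diameterMM / 2
  S0 <- ifelse(inside, 1, 0)
  newTissueMap(S0 = S0,
               T2StarMS = matrix(baseT2StarMS, nrow(S0), ncol(S0)),
               offResonanceHz = matrix(0, nrow(S0), ncol(S0)),
               dFdzHzPerMM = matrix(dFdzHzPerMM, nrow(S0), ncol(S0)),
               fatFraction = matrix(0, nrow(S0), ncol(S0)),
               geometry = geom, truth = list(objectMask = inside))
}

# ---------------------------------------------------------------------------
# Heart phantom
# ---------------------------------------------------------------------------

#' Specification of the dynamic mid-ventricular heart phantom
#'
#' Default per-segment end-diastolic and end-systolic T2* values are the
#' CINE mid-ventricular reference rows (segments 7-12, ms):
#' ED 16.8, 17.3, 16.3, 12.0, 11.4, 12.5; ES 13.7, 17.4, 14.8, 10.5, 8.3,
#' 10.9. The cycle is driven by a fractional modulation amplitude (default
#' 0.27, i.e. cycle max/min = 1.27) anchored at the end-diastolic values;
#' the ES row is retained as metadata. Default end-systolic epicardial
#' radius conserves myocardial cross-sectional area (incompressible wall).
#'
#' @param endoRadiusEDMM,epiRadiusEDMM end-diastolic endo/epicardial radii
#'   (mm), defaults 24 and 32.
#' @param endoRadiusESMM end-systolic endocardial radius (mm), default 14.
#' @param epiRadiusESMM end-systolic epicardial radius; default NA derives it
#'   from wall-area conservation.
#' @param segmentT2StarEDMS,segmentT2StarESMS numeric(6), per-segment T2*
#'   (ms) at end-diastole / end-systole, segments 7-12.
#' @param modulationAmplitude fractional cycle modulation a: per-segment
#'   cycle max/min = 1 + a. Default 0.27.
#' @param backgroundFieldCoef named numeric polynomial coefficients of the
#'   background field over mm coordinates (x toward anterolateral, y toward
#'   inferior): offset (Hz), x, y (Hz/mm), xy, x2my2 (Hz/mm^2).
#' @param epicardialGradientHzPerMM peak in-plane gradient of the localized
#'   epicardial perturbation (Hz/mm), default 20.
#' @param epicardialGradientAngleDeg angular position of the perturbation,
#'   counterclockwise from anterior; default 210 (inferior/inferolateral).
#' @param baseDFdzHzPerMM background through-plane gradient, default 3 Hz/mm.
#' @param epiDFdzHzPerMM through-plane gradient at the epicardial
#'   perturbation, default 20 Hz/mm.
#' @param heartRateBPM heart rate, default 60.
#' @param nPhases cardiac phases, default 25.
#' @param endDiastolicGapMS prospective-trigger gap, default 100 ms.
#' @param systoleFraction position of end-systole in the normalized cycle,
#'   default 0.35.
#' @param insertionAngleDeg anterior RV-insertion reference angle, default 0.
#' @param bloodT2StarMS,bloodS0 blood-pool parameters (defaults 20 ms, 1.3).
#' @param tissueT2StarMS,tissueS0 surrounding-tissue parameters (30 ms, 0.5).
#' @param chestRadiusMM radius of the surrounding tissue disc, default 70.
#' @return validated list of class \code{heartPhantomSpec}.
#' @export
heartPhantomSpec <- function(endoRadiusEDMM = 24, epiRadiusEDMM = 32,
                             endoRadiusESMM = 14, epiRadiusESMM = NA,
                             segmentT2StarEDMS = c(16.8, 17.3, 16.3,
                                                   12.0, 11.4, 12.5),
                             segmentT2StarESMS = c(13.7, 17.4, 14.8,
                                                   10.5, 8.3, 10.9),
                             modulationAmplitude = 0.27,
                             backgroundFieldCoef = c(offset = 0, x = 2.0,
                                                     y = 2.5, xy = 0.04,
                                                     x2my2 = 0.05),
                             epicardialGradientHzPerMM = 20,
                             epicardialGradientAngleDeg = 210,
                             baseDFdzHzPerMM = 3, epiDFdzHzPerMM = 20,
                             heartRateBPM = 60, nPhases = 25L,
                             endDiastolicGapMS = 100,
                             systoleFraction = 0.35,
                             insertionAngleDeg = 0,
                             bloodT2StarMS = 20, bloodS0 = 1.3,
                             tissueT2StarMS = 30, tissueS0 = 0.5,
                             chestRadiusMM = 70) {
  if (is.na(epiRadiusESMM))
    epiRadiusESMM <- sqrt(epiRadiusEDMM^2 - endoRadiusEDMM^2 +
                          endoRadiusESMM^2)
  spec <- list(endoRadiusEDMM = endoRadiusEDMM,
               epiRadiusEDMM = epiRadiusEDMM,
               endoRadiusESMM = endoRadiusESMM,
               epiRadiusESMM = epiRadiusESMM,
               segmentT2StarEDMS = segmentT2StarEDMS,
               segmentT2StarESMS = segmentT2StarESMS,
               modulationAmplitude = modulationAmplitude,
               backgroundFieldCoef = backgroundFieldCoef,
               epicardialGradientHzPerMM = epicardialGradientHzPerMM,
               epicardialGradientAngleDeg = epicardialGradientAngleDeg,
               baseDFdzHzPerMM = baseDFdzHzPerMM,
               epiDFdzHzPerMM = epiDFdzHzPerMM,
               heartRateBPM = heartRateBPM, nPhases = as.integer(nPhases),
               endDiastolicGapMS = endDiastolicGapMS,
               systoleFraction = systoleFraction,
               insertionAngleDeg = insertionAngleDeg,
               bloodT2StarMS = bloodT2StarMS, bloodS0 = bloodS0,
               tissueT2StarMS = tissueT2StarMS, tissueS0 = tissueS0,
               chestRadiusMM = chestRadiusMM)
  if (any(c(spec$segmentT2StarEDMS, spec$segmentT2StarESMS) <= 0))
    stop("segment T2* values must be positive")
  if (length(spec$segmentT2StarEDMS) != 6L ||
      length(spec$segmentT2StarESMS) != 6L)
    stop("six segment T2* values are required (segments 7-12)")
  if (spec$endoRadiusESMM >= spec$endoRadiusEDMM)
    stop("end-systolic endocardial radius must be smaller than diastolic")
  wallED <- spec$epiRadiusEDMM - spec$endoRadiusEDMM
  wallES <- spec$epiRadiusESMM - spec$endoRadiusESMM
  if (wallES <= wallED)
    stop("systolic wall thickness must exceed diastolic wall thickness")
  if (spec$modulationAmplitude < 0)
    stop("modulation amplitude must be non-negative")
  class(spec) <- "heartPhantomSpec"
  spec
}

# Contraction weight over the normalized cycle s in [0, 1): 0 at
# end-diastole (s = 0), rising to 1 at end-systole (s = sSys) by a raised
# cosine, relaxing back to 0 by s = sSys + 0.25, then a diastasis plateau.
contractionWeight <- function(s, sSys = 0.35) {
  s <- s %% 1
  relaxEnd <- sSys + 0.25
  w <- numeric(length(s))
  up <- s <= sSys
  w[up] <- (1 - cos(pi * s[up] / sSys)) / 2
  dn <- s > sSys & s <= relaxEnd
  w[dn] <- (1 + cos(pi * (s[dn] - sSys) / (relaxEnd - sSys))) / 2
  w
}

#' Dynamic mid-ventricular short-axis heart phantom
#'
#' An annular myocardium around a blood pool, inside a surrounding tissue
#' disc, rendered over \code{nPhases} cardiac phases at the prospective
#' trigger delays of \code{\link{triggerSchedule}}. Radii follow an
#' incompressible-wall radial contraction between the end-diastolic and
#' end-systolic values; each 60-degree sector carries its segment's T2*,
#' modulated over the cycle so the minimum falls in systole and the maximum
#' on the diastolic plateau, with cycle max/min equal to
#' \code{1 + modulationAmplitude}. The off-resonance field is a smooth
#' background polynomial plus a localized epicardial perturbation at the
#' inferior/inferolateral border.
#'
#' Ground truth recorded in \code{truth}: per-phase myocardial and cavity
#' masks, centre, per-phase per-segment labels and T2* values, cavity areas.
#'
#' @param spec a \code{\link{heartPhantomSpec}}.
#' @param geom \linkS4class{ImageGeometry}; default 128 x 128 over
#'   (288 x 288) mm^2, 4 mm slice.
#' @param transform optional \linkS4class{AffineTransform2D} in 0-based
#'   voxel coordinates: the anatomy is rendered displaced by it (the
#'   phantom is evaluated analytically on the transformed grid, so a
#'   breath-hold misalignment introduces no resampling error).
#' @return a time-resolved \linkS4class{TissueMap}.
#' @export
makeHeartPhantom <- function(spec = heartPhantomSpec(),
                             geom = imageGeometry(c(128L, 128L),
                                                  c(288, 288), 4),
                             transform = NULL) {
  if (!inherits(spec, "heartPhantomSpec")) stop("spec must be a heartPhantomSpec")
  nP <- spec$nPhases
  if (nP < 2L) stop("a dynamic heart phantom needs at least 2 cardiac phases")
  cc <- voxelCoordsMM(geom)
  n <- geom@matrixSize
  if (!is.null(transform)) {
    # anatomy coordinate of each output voxel: pull back through the
    # inverse transform (voxel units), then re-express in mm from centre
    res <- resolutionMM(geom)
    grid <- cbind(x = rep(0:(n[2] - 1), each = n[1]),
                  y = rep(0:(n[1] - 1), n[2]))
    src <- transformPoints(invertAffine(transform), grid)
    cc$x <- matrix((src[, 1] + 0.5 - n[2] / 2) * res[2], n[1], n[2])
    cc$y <- matrix((src[, 2] + 0.5 - n[1] / 2) * res[1], n[1], n[2])
  }
  rr <- sqrt(cc$x^2 + cc$y^2)
  ang <- ccwAngleDeg(cc$x, cc$y)
  secIdx <- floor(((ang - spec$insertionAngleDeg) %% 360) / 60) + 1L

  cycleMS <- 60000 / spec$heartRateBPM
  delays <- triggerSchedule(spec$heartRateBPM, nP, spec$endDiastolicGapMS)
  sNorm <- delays / cycleMS

  # static field maps (field geometry does not follow the contraction; field
  # maps show negligible temporal variation across the cycle)
  bf <- spec$backgroundFieldCoef
  df2d <- bf["offset"] + bf["x"] * cc$x + bf["y"] * cc$y +
    bf["xy"] * cc$x * cc$y + bf["x2my2"] * (cc$x^2 - cc$y^2)
  sigmaMM <- 2
  ampHz <- spec$epicardialGradientHzPerMM * sigmaMM * exp(0.5)
  thetaG <- spec$epicardialGradientAngleDeg * pi / 180
  # position on the (diastolic) epicardial border; angle measured ccw from
  # anterior: x = -R sin(theta), y = -R cos(theta)
  gx <- -spec$epiRadiusEDMM * sin(thetaG)
  gy <- -spec$epiRadiusEDMM * cos(thetaG)
  d2 <- (cc$x - gx)^2 + (cc$y - gy)^2
  df2d <- df2d + ampHz * exp(-d2 / (2 * sigmaMM^2))
  sigmaZ <- 4
  dfdz2d <- spec$baseDFdzHzPerMM +
    (spec$epiDFdzHzPerMM - spec$baseDFdzHzPerMM) * exp(-d2 / (2 * sigmaZ^2))

  A <- spec$modulationAmplitude / (1 + spec$modulationAmplitude)
  dims <- c(n[1], n[2], nP)
  S0 <- array(0, dims); T2 <- array(1, dims)
  DF <- array(0, dims); DZ <- array(0, dims); FF <- array(0, dims)
  myo <- array(FALSE, dims); cav <- array(FALSE, dims)
  labels <- array(NA_integer_, dims)
  cavityAreaVox <- numeric(nP)
  segAreaVox <- matrix(0, nP, 6, dimnames = list(NULL, paste0("seg", 7:12)))
  wallAreaVox <- numeric(nP)

  chest <- rr <= spec$chestRadiusMM
  for (p in seq_len(nP)) {
    w <- contractionWeight(sNorm[p], spec$systoleFraction)
    rEndo <- sqrt((1 - w) * spec$endoRadiusEDMM^2 + w * spec$endoRadiusESMM^2)
    rEpi <- sqrt((1 - w) * spec$epiRadiusEDMM^2 + w * spec$epiRadiusESMM^2)
    inCav <- rr <= rEndo
    inMyo <- rr > rEndo & rr <= rEpi
    s0p <- ifelse(chest, spec$tissueS0, 0)
    t2p <- matrix(spec$tissueT2StarMS, n[1], n[2])
    s0p[inCav] <- spec$bloodS0
    t2p[inCav] <- spec$bloodT2StarMS
    s0p[inMyo] <- 1
    m <- 1 - A * w  # cycle modulation: min in systole, max on the plateau
    for (k in 1:6) {
      vox <- inMyo & secIdx == k
      t2p[vox] <- spec$segmentT2StarEDMS[k] * m
      segAreaVox[p, k] <- sum(vox)
    }
    S0[, , p] <- s0p; T2[, , p] <- t2p
    DF[, , p] <- df2d; DZ[, , p] <- dfdz2d
    myo[, , p] <- inMyo; cav[, , p] <- inCav
    lab <- matrix(NA_integer_, n[1], n[2])
    lab[inMyo] <- 6L + secIdx[inMyo]
    labels[, , p] <- lab
    cavityAreaVox[p] <- sum(inCav)
    wallAreaVox[p] <- sum(inMyo)
  }
  segT2 <- outer(1 - A * contractionWeight(sNorm, spec$systoleFraction),
                 spec$segmentT2StarEDMS)
  colnames(segT2) <- paste0("seg", 7:12)
  newTissueMap(S0 = S0, T2StarMS = T2, offResonanceHz = DF,
               dFdzHzPerMM = DZ, fatFraction = FF, geometry = geom,
               phaseTimesMS = delays,
               truth = list(spec = spec, myoMask = myo, cavityMask = cav,
                            segmentLabels = labels,
                            centerVox = c(x = n[2] / 2 - 0.5,
                                          y = n[1] / 2 - 0.5),
                            cavityAreaVox = cavityAreaVox,
                            wallAreaVox = wallAreaVox,
                            segAreaVox = segAreaVox,
                            segmentT2StarMS = segT2,
                            phaseNorm = sNorm))
}

# ---------------------------------------------------------------------------
# Breath-hold misalignment
# ---------------------------------------------------------------------------

#' Apply random breath-hold misalignments to a phantom
#'
#' Each breath-hold receives an independent small affine perturbation
#' (translation plus shear) drawn from the seed; the applied transform is
#' recorded in \code{truth$appliedTransform} for registration tests. For the
#' analytic heart phantom the displaced anatomy is re-rendered exactly on
#' the transformed grid; grid-only phantoms are resampled with bilinear
#' interpolation.
#'
#' @param tissue a \linkS4class{TissueMap}.
#' @param nHolds number of breath-holds (>= 1).
#' @param shiftVox maximum |translation| per axis in voxels, default 2.
#' @param shearMag maximum |shear| (off-diagonal of the linear part),
#'   default 0.05.
#' @param seed integer seed.
#' @return list of \code{nHolds} TissueMaps.
#' @export
perturbBreathHolds <- function(tissue, nHolds, shiftVox = 2, shearMag = 0.05,
                               seed = 1L) {
  if (nHolds < 1L) stop("need at least one breath-hold")
  set.seed(as.integer(seed))
  lapply(seq_len(nHolds), function(h) {
    A <- matrix(c(1, stats::runif(1, -shearMag, shearMag),
                  stats::runif(1, -shearMag, shearMag), 1), 2, 2)
    tvec <- stats::runif(2, -shiftVox, shiftVox)
    tf <- affineTransform2D(A, tvec)
    out <- if (!is.null(tissue@truth$spec))
      makeHeartPhantom(tissue@truth$spec, tissue@geometry, transform = tf)
    else transformTissueMap(tissue, tf)
    out@truth$appliedTransform <- tf
    out@truth$hold <- h
    out
  })
}

# Resample every field of a TissueMap under a forward affine (reference ->
# hold coordinates). Masks are resampled with the same interpolator and
# re-thresholded; labels recomputed from the mask and sector geometry are
# not needed here because downstream segmentation re-derives them.
transformTissueMap <- function(tissue, tf) {
  nP <- nPhases(tissue)
  doField <- function(arr, outside = 0) {
    out <- arr
    for (p in seq_len(nP))
      out[, , p] <- warpImage(arr[, , p], tf, outside = outside)
    out
  }
  S0 <- doField(tissue@S0)
  T2 <- doField(tissue@T2StarMS, outside = 1)
  T2 <- pmax(T2, 0.01)
  out <- newTissueMap(S0 = S0, T2StarMS = T2,
                      offResonanceHz = doField(tissue@offResonanceHz),
                      dFdzHzPerMM = doField(tissue@dFdzHzPerMM),
                      fatFraction = pmin(pmax(doField(tissue@fatFraction), 0), 1),
                      geometry = tissue@geometry,
                      phaseTimesMS = tissue@phaseTimesMS,
                      truth = tissue@truth)
  if (!is.null(tissue@truth$myoMask)) {
    warpMask <- function(m) {
      w <- array(FALSE, dim(m))
      for (p in seq_len(nP))
        w[, , p] <- warpImage(m[, , p] * 1, tf, outside = 0) > 0.5
      w
    }
    out@truth$myoMask <- warpMask(tissue@truth$myoMask)
    out@truth$cavityMask <- warpMask(tissue@truth$cavityMask)
  }
  out
}

#' Extract one cardiac phase as a static phantom
#'
#' Returns a single-phase \linkS4class{TissueMap} frozen at the given frame,
#' with the per-phase ground-truth masks subset accordingly — the fixture
#' for experiments that need a motionless anatomy.
#'
#' @param tissue a time-resolved \linkS4class{TissueMap}.
#' @param phase frame index, default 1 (the end-diastolic frame for the
#'   heart phantom).
#' @return a \linkS4class{TissueMap} with one cardiac phase.
#' @export
phantomFrame <- function(tissue, phase = 1L) {
  sub <- function(a) a[, , phase, drop = FALSE]
  truth <- tissue@truth
  for (nm in c("myoMask", "cavityMask", "segmentLabels"))
    if (!is.null(truth[[nm]])) truth[[nm]] <- sub(truth[[nm]])
  for (nm in c("cavityAreaVox", "wallAreaVox", "phaseNorm"))
    if (!is.null(truth[[nm]])) truth[[nm]] <- truth[[nm]][phase]
  if (!is.null(truth$segAreaVox))
    truth$segAreaVox <- truth$segAreaVox[phase, , drop = FALSE]
  if (!is.null(truth$segmentT2StarMS))
    truth$segmentT2StarMS <- truth$segmentT2StarMS[phase, , drop = FALSE]
  truth$spec <- NULL  # frozen frame is no longer the analytic dynamic model
  newTissueMap(S0 = sub(tissue@S0), T2StarMS = sub(tissue@T2StarMS),
               offResonanceHz = sub(tissue@offResonanceHz),
               dFdzHzPerMM = sub(tissue@dFdzHzPerMM),
               fatFraction = sub(tissue@fatFraction),
               geometry = tissue@geometry,
               phaseTimesMS = tissue@phaseTimesMS[phase], truth = truth)
}
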