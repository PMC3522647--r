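# B0 field mapping from dual-echo phase images, volume-selective shim
# optimization with a linear + second-order basis, and field statistics.

#' B0 field map from a dual-echo phase difference
#'
#' \code{df = wrap(phi2 - phi1) / (2 pi dTE)}, with the wrapped difference in
#' [-pi, pi), confining the map to the Nyquist band +-1/(2 dTE); true offsets
#' beyond that band alias. No spatial unwrapping is performed.
#'
#' @param phase1,phase2 phase images (radians) at the two echo times.
#' @param te1MS,te2MS echo times (ms), \code{te2MS > te1MS}.
#' @param mask optional logical matrix of valid voxels (default all TRUE).
#' @param geom optional \linkS4class{ImageGeometry}; default inferred with
#'   1 mm isotropic resolution.
#' @return a \linkS4class{FieldMap}.
#' @examples
#' computeB0Map(matrix(0, 2, 2), matrix(pi / 2, 2, 2), 2.04, 3.06)
#' @export
computeB0Map <- function(phase1, phase2, te1MS, te2MS, mask = NULL,
                         geom = NULL) {
  if (te2MS <= te1MS) stop("TE2 must exceed TE1")
  if (!identical(dim(phase1), dim(phase2)))
    stop("phase images must share dimensions")
  dTE <- te2MS - te1MS
  df <- wrapPhase(phase2 - phase1) / (2 * pi * dTE / 1000)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(df), ncol(df))
  fieldMap(df, mask = mask & is.finite(df), dTEms = dTE, geom = geom)
}

#' B0 map from the first two echoes of an image series
#'
#' Convenience wrapper applying \code{\link{computeB0Map}} to the two
#' earliest echoes of one cardiac phase of a series (the offline field
#' mapping route: phase images of the first two echoes of the interleaved
#' multi-shot acquisition).
#'
#' @param series an \linkS4class{EchoImageSeries}.
#' @param phase cardiac phase to use, default 1.
#' @param mask optional validity mask; default voxels with non-zero
#'   magnitude at the first echo.
#' @return a \linkS4class{FieldMap}.
#' @export
b0MapFromSeries <- function(series, phase = 1L, mask = NULL) {
  fi <- frameInfo(series)
  sel <- fi[fi$phase == phase, ]
  sel <- sel[order(sel$teMS), ]
  if (nrow(sel) < 2L) stop("need at least two echoes for field mapping")
  f1 <- sel$frame[1]; f2 <- sel$frame[2]
  dat <- seriesData(series)
  if (is.null(mask)) mask <- Mod(dat[, , f1]) > 0
  computeB0Map(Arg(dat[, , f1]), Arg(dat[, , f2]), sel$teMS[1], sel$teMS[2],
               mask = mask, geom = geometry(series))
}

# shim basis over mm coordinates relative to the ROI centroid; z-dependent
# terms are dropped for the 2D single-slice case
shimBasis <- function(x, y, order) {
  B <- cbind(offset = rep(1, length(x)), x = x, y = y)
  if (order >= 2L) B <- cbind(B, x2my2 = x^2 - y^2, xy = x * y)
  B
}

#' Volume-selective shim fit
#'
#' Least-squares fit of the shim basis (offset + linear terms; order 2 adds
#' the in-plane second-order terms x^2 - y^2 and xy) to the field over the
#' ROI, with coordinates in mm relative to the ROI centroid. Shimming is
#' field-surface subtraction: the shimmed map is \code{field - fit}. The
#' least-squares projection cannot increase the ROI RMS.
#'
#' @param fieldMap a \linkS4class{FieldMap}.
#' @param roi logical matrix, non-empty, within the map's mask.
#' @param order 1 (linear) or 2 (default).
#' @return a \linkS4class{ShimSolution}.
#' @export
fitShim <- function(fieldMap, roi, order = 2L) {
  order <- as.integer(order)
  if (!order %in% 1:2) stop("shim order must be 1 or 2")
  roi <- roi & fieldMap@mask
  nRoi <- sum(roi)
  if (nRoi == 0L) stop("ROI is empty")
  cc <- voxelCoordsMM(fieldMap@geometry)
  xs <- cc$x[roi]; ys <- cc$y[roi]
  xs0 <- xs - mean(xs); ys0 <- ys - mean(ys)
  B <- shimBasis(xs0, ys0, order)
  if (nRoi < ncol(B))
    stop("ROI smaller than the shim basis")
  f <- fieldMap@offResonanceHz[roi]
  beta <- qr.coef(qr(B), f)
  beta[is.na(beta)] <- 0
  fittedRoi <- drop(B %*% beta)
  Ball <- shimBasis(as.vector(cc$x) - mean(xs), as.vector(cc$y) - mean(ys),
                    order)
  fittedAll <- matrix(drop(Ball %*% beta), nrow(roi), ncol(roi))
  resid <- f - fittedRoi
  stats <- c(prePeakToPeakHz = diff(range(f)),
             postPeakToPeakHz = diff(range(resid)),
             preRMSHz = sqrt(mean(f^2)),
             postRMSHz = sqrt(mean(resid^2)))
  new("ShimSolution", coefficients = beta, order = order, roi = roi,
      fittedHz = fittedAll, stats = stats)
}

#' Apply a shim solution to a field map
#'
#' Subtracts the fitted shim surface; the result is wrapped back into the
#' phase-difference Nyquist band, as re-measuring the field under the
#' applied shim would. Far outside the fitted ROI the extrapolated surface
#' can be large, so aliasing there is expected.
#'
#' @param fieldMap a \linkS4class{FieldMap}.
#' @param shim a \linkS4class{ShimSolution} fitted on this map's grid.
#' @return the shimmed \linkS4class{FieldMap} (field minus fitted surface).
#' @export
applyShim <- function(fieldMap, shim) {
  df <- fieldMap@offResonanceHz - shim@fittedHz
  if (!fieldMap@unwrapped) {
    scale <- 2 * pi * fieldMap@dTEms / 1000
    df <- wrapPhase(df * scale) / scale
  }
  new("FieldMap", offResonanceHz = df, mask = fieldMap@mask,
      dTEms = fieldMap@dTEms, unwrapped = fieldMap@unwrapped,
      geometry = fieldMap@geometry)
}

#' Field statistics over an ROI
#'
#' Peak-to-peak range, histogram full width at half maximum (10 Hz bins with
#' linear interpolation at the half-maximum crossings), and maximum and mean
#' per-voxel in-plane gradient magnitude |grad f| from finite differences
#' between neighbouring ROI voxels (a 3 Hz/mm ramp reports a mean gradient
#' of 3 Hz/mm).
#'
#' @param fieldMap a \linkS4class{FieldMap}.
#' @param roi logical matrix, non-empty.
#' @param binWidthHz histogram bin width for the FWHM, default 10 Hz.
#' @return named numeric: \code{peakToPeakHz}, \code{fwhmHz},
#'   \code{maxGradientHzPerMM}, \code{meanGradientHzPerMM} (gradients NA and
#'   flagged by attribute \code{gradientDefined = FALSE} for a single-voxel
#'   ROI).
#' @export
fieldStats <- function(fieldMap, roi, binWidthHz = 10) {
  roi <- roi & fieldMap@mask
  if (!any(roi)) stop("ROI is empty")
  f <- fieldMap@offResonanceHz
  v <- f[roi]
  pp <- diff(range(v))
  fwhm <- histogramFWHM(v, binWidthHz)
  res <- resolutionMM(fieldMap@geometry)
  nr <- nrow(f); nc <- ncol(f)
  # per-voxel axis gradients averaged over the voxel's in-ROI neighbour
  # pairs; NA where no neighbour exists along that axis
  axisGrad <- function(shiftRows) {
    num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
    if (shiftRows) {
      both <- roi[-nr, ] & roi[-1, ]
      d <- (f[-1, ] - f[-nr, ]) / res[1]
      num[-nr, ][both] <- num[-nr, ][both] + d[both]
      den[-nr, ][both] <- den[-nr, ][both] + 1
      num[-1, ][both] <- num[-1, ][both] + d[both]
      den[-1, ][both] <- den[-1, ][both] + 1
    } else {
      both <- roi[, -nc] & roi[, -1]
      d <- (f[, -1] - f[, -nc]) / res[2]
      num[, -nc][both] <- num[, -nc][both] + d[both]
      den[, -nc][both] <- den[, -nc][both] + 1
      num[, -1][both] <- num[, -1][both] + d[both]
      den[, -1][both] <- den[, -1][both] + 1
    }
    ifelse(den > 0, num / den, NA_real_)
  }
  gy <- axisGrad(TRUE); gx <- axisGrad(FALSE)
  hasAny <- roi & (!is.na(gx) | !is.na(gy))
  mag <- sqrt(ifelse(is.na(gx), 0, gx)^2 + ifelse(is.na(gy), 0, gy)^2)
  grads <- mag[hasAny]
  out <- c(peakToPeakHz = pp, fwhmHz = fwhm,
           maxGradientHzPerMM = if (length(grads)) max(grads) else NA_real_,
           meanGradientHzPerMM = if (length(grads)) mean(grads) else NA_real_)
  attr(out, "gradientDefined") <- length(grads) > 0
  out
}

# FWHM of the binned histogram, linear interpolation between bin midpoints
# at the half-maximum crossings; 0 when all values fall in one bin
histogramFWHM <- function(v, binWidthHz = 10) {
  if (diff(range(v)) < binWidthHz) return(0)
  breaks <- seq(floor(min(v) / binWidthHz) * binWidthHz,
                ceiling(max(v) / binWidthHz) * binWidthHz, by = binWidthHz)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  half <- max(counts) / 2
  above <- which(counts >= half)
  iL <- above[1]; iR <- above[length(above)]
  left <- if (iL == 1) mids[1] else
    mids[iL - 1] + binWidthHz * (half - counts[iL - 1]) /
      (counts[iL] - counts[iL - 1])
  n <- length(counts)
  right <- if (iR == n) mids[n] else
    mids[iR] + binWidthHz * (counts[iR] - half) /
      (counts[iR] - counts[iR + 1])
  max(right - left, 0)
}

#' Intravoxel frequency dispersion from a gradient and a voxel extent
#'
#' The product gradient (Hz/mm) times voxel extent (mm): e.g. a 3 Hz/mm
#' through-plane gradient over a 4 mm slice gives 12 Hz/voxel; 20 Hz/mm
#' gives 80 Hz/voxel.
#'
#' @param gradientHzPerMM field gradient (Hz/mm), >= 0.
#' @param extentMM voxel extent along the gradient (mm), >= 0.
#' @return dispersion in Hz per voxel.
#' @export
dispersionPerVoxel <- function(gradientHzPerMM, extentMM) {
  if (any(gradientHzPerMM < 0) || any(extentMM < 0))
    stop("inputs must be non-negative")
  gradientHzPerMM * extentMM
}

#' Mean gradient implied by a field span over a distance
#'
#' E.g. an 80 Hz peak-to-peak variation along 40 mm corresponds to 2 Hz/mm.
#'
#' @param spanHz field variation (Hz).
#' @param distanceMM distance over which it occurs (mm), > 0.
#' @return gradient in Hz/mm.
#' @export
fieldSpanToGradient <- function(spanHz, distanceMM) {
  if (any(distanceMM <= 0)) stop("distance must be positive")
  spanHz / distanceMM
}
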