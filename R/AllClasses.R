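#' @import methods
NULL

# ---------------------------------------------------------------------------
# ImageGeometry
# ---------------------------------------------------------------------------

#' Image geometry of a 2D (single-slice) acquisition
#'
#' Describes the sampling grid of a single-slice cardiac acquisition: matrix
#' size (rows x columns), field of view in mm, slice thickness in mm, and a
#' slice-orientation label. In-plane resolution is always \code{FOV / matrix}
#' and is exposed through \code{\link{resolutionMM}} rather than stored.
#'
#' Coordinate convention used throughout the package: voxel indices are
#' 0-based with half-open extents; the centre of voxel \code{(i, j)} (row i,
#' column j) sits at mm coordinates \code{((i + 0.5) * res_row, (j + 0.5) *
#' res_col)} relative to the image corner. \code{\link{voxelCoordsMM}} returns
#' coordinates relative to the image centre, which is what the phantoms and
#' the shim basis use. For short-axis views the image row axis runs
#' anterior (top) to inferior (bottom).
#'
#' @slot matrixSize integer(2), rows x columns.
#' @slot fovMM numeric(2), field of view along (rows, columns) in mm.
#' @slot sliceThicknessMM numeric(1), slice thickness in mm.
#' @slot orientation character(1), one of \code{"short-axis"},
#'   \code{"four-chamber"}, \code{"axial"}.
#' @export
setClass("ImageGeometry",
  representation(matrixSize = "integer", fovMM = "numeric",
                 sliceThicknessMM = "numeric", orientation = "character"))

setValidity("ImageGeometry", function(object) {
  msg <- character(0)
  if (length(object@matrixSize) != 2L || any(object@matrixSize <= 0L))
    msg <- c(msg, "matrixSize must be two positive integers (rows, columns)")
  if (length(object@fovMM) != 2L || any(object@fovMM <= 0))
    msg <- c(msg, "fovMM must be two strictly positive extents")
  if (length(object@sliceThicknessMM) != 1L || object@sliceThicknessMM <= 0)
    msg <- c(msg, "sliceThicknessMM must be a single positive value")
  if (!object@orientation %in% c("short-axis", "four-chamber", "axial"))
    msg <- c(msg, "orientation must be short-axis, four-chamber or axial")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageGeometry
#'
#' Defaults reproduce the in vivo protocol: 256 x 224 matrix over a
#' (288 x 252) mm^2 field of view (1.125 mm in-plane resolution, printed as
#' 1.1 mm), 4 mm slice thickness, short-axis orientation.
#'
#' @param matrixSize integer(2) rows x columns.
#' @param fovMM numeric(2) field of view in mm along (rows, columns).
#' @param sliceThicknessMM slice thickness in mm.
#' @param orientation slice orientation label.
#' @return An \linkS4class{ImageGeometry}.
#' @examples
#' g <- imageGeometry()
#' resolutionMM(g)
#' @export
imageGeometry <- function(matrixSize = c(256L, 224L),
                          fovMM = c(288, 252),
                          sliceThicknessMM = 4,
                          orientation = "short-axis") {
  new("ImageGeometry", matrixSize = as.integer(matrixSize),
      fovMM = as.numeric(fovMM),
      sliceThicknessMM = as.numeric(sliceThicknessMM),
      orientation = orientation)
}

# ---------------------------------------------------------------------------
# TissueMap
# ---------------------------------------------------------------------------

#' Voxelized ground-truth tissue parameter fields
#'
#' Holds per-voxel equilibrium signal S0 (arbitrary units), effective
#' transverse relaxation time T2* (ms), off-resonance frequency offset
#' (Hz), through-plane field gradient (Hz/mm), and fat fraction, on a common
#' geometry, optionally resolved over the cardiac cycle (third array index =
#' cardiac phase). \code{phaseTimesMS} gives the time of each frame after the
#' cardiac trigger. The \code{truth} list carries generator bookkeeping used
#' by tests and downstream analysis (myocardial/cavity masks, per-phase
#' centres, segment labels, applied breath-hold transforms).
#'
#' @slot S0 3D array (rows x cols x phases), 0 outside the object.
#' @slot T2StarMS 3D array, ms; strictly positive inside the object.
#' @slot offResonanceHz 3D array, off-resonance in Hz.
#' @slot dFdzHzPerMM 3D array, through-plane field gradient in Hz/mm.
#' @slot fatFraction 3D array in [0, 1].
#' @slot geometry \linkS4class{ImageGeometry}.
#' @slot phaseTimesMS numeric, trigger delay of each frame in ms.
#' @slot truth list of generator ground truth.
#' @export
setClass("TissueMap",
  representation(S0 = "array", T2StarMS = "array", offResonanceHz = "array",
                 dFdzHzPerMM = "array", fatFraction = "array",
                 geometry = "ImageGeometry", phaseTimesMS = "numeric",
                 truth = "list"))

setValidity("TissueMap", function(object) {
  msg <- character(0)
  dm <- dim(object@S0)
  if (length(dm) != 3L)
    msg <- c(msg, "parameter fields must be rows x cols x phases arrays")
  for (sl in c("T2StarMS", "offResonanceHz", "dFdzHzPerMM", "fatFraction"))
    if (!identical(dim(slot(object, sl)), dm))
      msg <- c(msg, sprintf("dim(%s) must match dim(S0)", sl))
  if (!identical(dm[1:2], as.integer(object@geometry@matrixSize)))
    msg <- c(msg, "field dimensions must match geometry matrix size")
  if (length(object@phaseTimesMS) != dm[3])
    msg <- c(msg, "phaseTimesMS must have one entry per cardiac phase")
  inside <- object@S0 > 0
  if (any(object@T2StarMS[inside] <= 0))
    msg <- c(msg, "T2* must be strictly positive inside the object")
  if (any(!is.finite(object@offResonanceHz)))
    msg <- c(msg, "off-resonance must be finite everywhere")
  if (any(object@fatFraction < 0 | object@fatFraction > 1))
    msg <- c(msg, "fat fraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

# internal constructor: promote matrices to 1-phase arrays
newTissueMap <- function(S0, T2StarMS, offResonanceHz, dFdzHzPerMM,
                         fatFraction, geometry, phaseTimesMS = 0,
                         truth = list()) {
  as3 <- function(x) {
    if (length(dim(x)) == 2L) array(x, dim = c(dim(x), 1L)) else x
  }
  new("TissueMap", S0 = as3(S0), T2StarMS = as3(T2StarMS),
      offResonanceHz = as3(offResonanceHz), dFdzHzPerMM = as3(dFdzHzPerMM),
      fatFraction = as3(fatFraction), geometry = geometry,
      phaseTimesMS = as.numeric(phaseTimesMS), truth = truth)
}

# ---------------------------------------------------------------------------
# SequenceParams
# ---------------------------------------------------------------------------

#' Spoiled gradient-echo sequence parameters
#'
#' @slot teMS numeric, echo times in ms, strictly increasing and positive.
#' @slot trMS numeric(1), repetition time in ms, larger than max(TE).
#' @slot flipDeg numeric(1), nominal flip angle in degrees, in (0, 90].
#' @slot noiseSigma numeric(1), receiver noise standard deviation per
#'   real/imaginary channel (arbitrary units, same scale as S0).
#' @slot f0MHz numeric(1), proton resonance frequency in MHz (297.2 at 7 T).
#' @slot fatShiftPPM numeric(1), fat-water chemical shift in ppm.
#' @slot t1MS numeric(1), longitudinal relaxation time in ms; NA disables the
#'   steady-state (T1 saturation) factor, which is the default because the
#'   mono-exponential decay model absorbs any TE-independent scale.
#' @export
setClass("SequenceParams",
  representation(teMS = "numeric", trMS = "numeric", flipDeg = "numeric",
                 noiseSigma = "numeric", f0MHz = "numeric",
                 fatShiftPPM = "numeric", t1MS = "numeric"))

setValidity("SequenceParams", function(object) {
  msg <- character(0)
  te <- object@teMS
  if (length(te) < 1L || any(te <= 0) || any(diff(te) <= 0))
    msg <- c(msg, "echo times must be positive and strictly increasing")
  if (object@trMS <= max(te))
    msg <- c(msg, "TR must exceed the largest echo time")
  if (object@flipDeg <= 0 || object@flipDeg > 90)
    msg <- c(msg, "flip angle must lie in (0, 90] degrees")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noise sigma must be non-negative")
  if (object@f0MHz <= 0) msg <- c(msg, "f0 must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct sequence parameters
#'
#' Defaults follow the 7 T protocol: nine echoes from 2.04 ms to 10.20 ms in
#' 1.02 ms steps (the fat-water in-phase spacing at 297.2 MHz / 3.3 ppm),
#' 20 degree nominal flip angle.
#'
#' @param teMS echo times (ms).
#' @param trMS repetition time (ms).
#' @param flipDeg nominal flip angle (degrees).
#' @param noiseSigma receiver noise sd per channel (arbitrary units).
#' @param f0MHz proton frequency (MHz).
#' @param fatShiftPPM fat-water chemical shift (ppm).
#' @param t1MS T1 in ms, or NA to disable steady-state weighting.
#' @return A \linkS4class{SequenceParams}.
#' @examples
#' sequenceParams()@teMS
#' @export
sequenceParams <- function(teMS = echoSchedule(2.04, 1.02, 9),
                           trMS = 12, flipDeg = 20, noiseSigma = 0,
                           f0MHz = 297.2, fatShiftPPM = 3.3, t1MS = NA_real_) {
  new("SequenceParams", teMS = teMS, trMS = trMS, flipDeg = flipDeg,
      noiseSigma = noiseSigma, f0MHz = f0MHz, fatShiftPPM = fatShiftPPM,
      t1MS = as.numeric(t1MS))
}

# ---------------------------------------------------------------------------
# AcquisitionProtocol
# ---------------------------------------------------------------------------

#' Cardiac-triggered segmented acquisition protocol
#'
#' One of five strategies:
#' \describe{
#'   \item{ME}{single-phase multi-echo, one excitation acquiring all echoes.}
#'   \item{MS}{single-phase interleaved multi-shot: three excitations of
#'     three echoes each, shortening the effective inter-echo spacing.}
#'   \item{MB_CINE}{CINE with echoes interleaved over breath-holds: each
#'     breath-hold acquires the full k-space of one excitation's echo set.}
#'   \item{ME_CINE}{CINE multi-echo, one excitation.}
#'   \item{MS_CINE}{CINE interleaved multi-shot within one breath-hold.}
#' }
#'
#' @slot strategy character(1).
#' @slot nLines integer(1), number of phase-encode lines.
#' @slot viewsPerSegment integer(1), k-space lines acquired per cardiac cycle
#'   per image.
#' @slot echoesPerExcitation integer(1).
#' @slot nExcitations integer(1), interleaved excitations (1 or 3).
#' @slot teMS numeric, echo times (ms).
#' @slot trMS numeric(1), repetition time (ms).
#' @slot heartRateBPM numeric(1).
#' @slot nCardiacPhases integer(1), CINE phases (1 for single-phase).
#' @slot nBreathHolds integer(1) (>1 only for MB_CINE).
#' @slot prepCycles integer(1), preparatory cardiac cycles (default 1).
#' @slot triggerDelayMS numeric(1), acquisition window start for single-phase
#'   strategies (ms after trigger); NA places it at end-diastole.
#' @slot endDiastolicGapMS numeric(1), prospective-triggering gap (ms).
#' @export
setClass("AcquisitionProtocol",
  representation(strategy = "character", nLines = "integer",
                 viewsPerSegment = "integer", echoesPerExcitation = "integer",
                 nExcitations = "integer", teMS = "numeric", trMS = "numeric",
                 heartRateBPM = "numeric", nCardiacPhases = "integer",
                 nBreathHolds = "integer", prepCycles = "integer",
                 triggerDelayMS = "numeric", endDiastolicGapMS = "numeric"))

setValidity("AcquisitionProtocol", function(object) {
  msg <- character(0)
  if (!object@strategy %in% c("ME", "MS", "MB_CINE", "ME_CINE", "MS_CINE"))
    msg <- c(msg, "unknown strategy")
  if (object@nLines <= 0L) msg <- c(msg, "nLines must be positive")
  if (object@viewsPerSegment < 1L)
    msg <- c(msg, "views per segment must be >= 1")
  if (object@strategy %in% c("ME", "ME_CINE") && object@nExcitations != 1L)
    msg <- c(msg, "ME strategies use a single excitation")
  if (object@strategy %in% c("MS", "MS_CINE", "MB_CINE") &&
      object@nExcitations != 3L)
    msg <- c(msg, "interleaved strategies use three excitations")
  if (length(object@teMS) !=
      object@echoesPerExcitation * object@nExcitations)
    msg <- c(msg, "echo count must equal echoesPerExcitation * nExcitations")
  if (object@strategy == "MB_CINE" &&
      object@nBreathHolds != object@nExcitations)
    msg <- c(msg, "MB_CINE uses one breath-hold per excitation")
  if (object@strategy != "MB_CINE" && object@nBreathHolds != 1L)
    msg <- c(msg, "only MB_CINE spans multiple breath-holds")
  if (object@heartRateBPM <= 0) msg <- c(msg, "heart rate must be positive")
  if (object@nCardiacPhases < 1L) msg <- c(msg, "need >= 1 cardiac phase")
  if (grepl("CINE", object@strategy) && object@nCardiacPhases < 2L)
    msg <- c(msg, "CINE strategies need >= 2 cardiac phases")
  if (length(msg)) msg else TRUE
})

#' Protocol presets for the five acquisition strategies
#'
#' Returns the phantom-study protocol for a named strategy. Views per
#' segment follow the printed protocol (ME 10, MS 5, ME CINE 2, MS CINE 1,
#' MB CINE 3); repetition times are inferred from the printed acquisition
#' windows (205/192/36/38/36 ms), giving TR = 20.5 ms (ME), 12.8 ms (MS),
#' 12 ms (MB CINE and MS CINE), 19 ms (ME CINE). ME variants use 6 echoes
#' spaced 3.06 ms; interleaved variants use 9 echoes spaced 1.02 ms split
#' over three excitations.
#'
#' @param strategy one of "ME", "MS", "MB_CINE", "ME_CINE", "MS_CINE".
#' @param nLines phase-encode lines (240 in the phantom protocol).
#' @param heartRateBPM heart rate, default 60.
#' @param nCardiacPhases CINE phases, default 25.
#' @param viewsPerSegment override the preset views per segment.
#' @param trMS override the preset repetition time (ms).
#' @param prepCycles preparatory cardiac cycles, default 1.
#' @param triggerDelayMS single-phase window start (ms); NA = end-diastole.
#' @param endDiastolicGapMS prospective-trigger gap, default 100 ms.
#' @return An \linkS4class{AcquisitionProtocol}.
#' @examples
#' scanDuration(protocolPreset("ME", nLines = 240L))
#' @export
protocolPreset <- function(strategy, nLines = 240L, heartRateBPM = 60,
                           nCardiacPhases = 25L, viewsPerSegment = NULL,
                           trMS = NULL, prepCycles = 1L,
                           triggerDelayMS = NA_real_,
                           endDiastolicGapMS = 100) {
  strategy <- match.arg(strategy,
                        c("ME", "MS", "MB_CINE", "ME_CINE", "MS_CINE"))
  preset <- switch(strategy,
    ME      = list(vps = 10L, tr = 20.5, nexc = 1L, epe = 6L, dte = 3.06,
                   cine = FALSE, holds = 1L),
    MS      = list(vps = 5L,  tr = 12.8, nexc = 3L, epe = 3L, dte = 1.02,
                   cine = FALSE, holds = 1L),
    MB_CINE = list(vps = 3L,  tr = 12,   nexc = 3L, epe = 3L, dte = 1.02,
                   cine = TRUE,  holds = 3L),
    ME_CINE = list(vps = 2L,  tr = 19,   nexc = 1L, epe = 6L, dte = 3.06,
                   cine = FALSE, holds = 1L, cine2 = TRUE),
    MS_CINE = list(vps = 1L,  tr = 12,   nexc = 3L, epe = 3L, dte = 1.02,
                   cine = TRUE,  holds = 1L))
  isCine <- grepl("CINE", strategy)
  nEchoes <- preset$epe * preset$nexc
  new("AcquisitionProtocol", strategy = strategy,
      nLines = as.integer(nLines),
      viewsPerSegment = as.integer(
        if (is.null(viewsPerSegment)) preset$vps else viewsPerSegment),
      echoesPerExcitation = preset$epe, nExcitations = preset$nexc,
      teMS = echoSchedule(2.04, preset$dte, nEchoes),
      trMS = if (is.null(trMS)) preset$tr else trMS,
      heartRateBPM = heartRateBPM,
      nCardiacPhases = if (isCine) as.integer(nCardiacPhases) else 1L,
      nBreathHolds = preset$holds, prepCycles = as.integer(prepCycles),
      triggerDelayMS = triggerDelayMS,
      endDiastolicGapMS = endDiastolicGapMS)
}

# ---------------------------------------------------------------------------
# EchoImageSeries
# ---------------------------------------------------------------------------

#' Complex multi-echo image series
#'
#' Complex-valued images indexed by echo, cardiac phase and breath-hold.
#' Frames are stored as a rows x cols x frames array; \code{frameInfo} maps
#' each frame to its echo index, echo time, cardiac phase and breath-hold.
#' Magnitude and phase views are available via \code{\link{magnitudeData}}
#' and \code{\link{phaseData}} (phase in radians in [-pi, pi)).
#'
#' @slot data complex 3D array (rows x cols x frames).
#' @slot frameInfo data.frame with columns \code{frame}, \code{echo},
#'   \code{teMS}, \code{phase}, \code{hold}, sorted by (hold, phase, echo)
#'   with phases ordered by trigger delay.
#' @slot geometry \linkS4class{ImageGeometry}.
#' @slot protocol character(1), provenance label (strategy name or "none").
#' @export
setClass("EchoImageSeries",
  representation(data = "array", frameInfo = "data.frame",
                 geometry = "ImageGeometry", protocol = "character"))

setValidity("EchoImageSeries", function(object) {
  msg <- character(0)
  dm <- dim(object@data)
  if (length(dm) != 3L)
    msg <- c(msg, "data must be a rows x cols x frames array")
  if (!is.complex(object@data))
    msg <- c(msg, "data must be complex")
  need <- c("frame", "echo", "teMS", "phase", "hold")
  if (!all(need %in% names(object@frameInfo)))
    msg <- c(msg, paste("frameInfo needs columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@frameInfo) != dm[3])
      msg <- c(msg, "frameInfo must have one row per frame")
    combos <- unique(object@frameInfo[, c("echo", "phase", "hold")])
    if (nrow(combos) != nrow(object@frameInfo))
      msg <- c(msg, "duplicate (echo, phase, hold) frames")
  }
  if (!identical(dm[1:2], as.integer(object@geometry@matrixSize)))
    msg <- c(msg, "data dimensions must match geometry")
  if (length(msg)) msg else TRUE
})

newEchoImageSeries <- function(data, frameInfo, geometry,
                               protocol = "none") {
  o <- order(frameInfo$hold, frameInfo$phase, frameInfo$echo)
  frameInfo <- frameInfo[o, , drop = FALSE]
  data <- data[, , o, drop = FALSE]
  frameInfo$frame <- seq_len(nrow(frameInfo))
  rownames(frameInfo) <- NULL
  new("EchoImageSeries", data = data, frameInfo = frameInfo,
      geometry = geometry, protocol = protocol)
}

# ---------------------------------------------------------------------------
# FieldMap / ShimSolution
# ---------------------------------------------------------------------------

#' Off-resonance field map
#'
#' Per-voxel off-resonance in Hz derived from a dual-echo phase difference.
#' Unless flagged as unwrapped, values are confined to the phase-difference
#' Nyquist band +-1/(2 dTE); no spatial unwrapping is performed by the
#' mapping routines, but ground-truth or externally unwrapped maps may carry
#' values beyond the band with \code{unwrapped = TRUE}.
#'
#' @slot offResonanceHz numeric matrix (Hz).
#' @slot mask logical matrix of valid voxels.
#' @slot dTEms numeric(1), echo-time difference used (ms).
#' @slot unwrapped logical(1); TRUE lifts the Nyquist-band invariant.
#' @slot geometry \linkS4class{ImageGeometry}.
#' @export
setClass("FieldMap",
  representation(offResonanceHz = "matrix", mask = "matrix",
                 dTEms = "numeric", unwrapped = "logical",
                 geometry = "ImageGeometry"),
  prototype(unwrapped = FALSE))

setValidity("FieldMap", function(object) {
  msg <- character(0)
  if (!identical(dim(object@offResonanceHz), dim(object@mask)))
    msg <- c(msg, "mask and field dimensions must agree")
  if (object@dTEms <= 0) msg <- c(msg, "dTE must be positive")
  if (!isTRUE(object@unwrapped)) {
    nyq <- 1000 / (2 * object@dTEms)
    v <- object@offResonanceHz[object@mask]
    if (length(v) && any(abs(v) > nyq + 1e-9))
      msg <- c(msg,
               "masked field values exceed the phase-difference Nyquist band")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FieldMap
#' @param offResonanceHz numeric matrix (Hz).
#' @param mask logical matrix; default all TRUE.
#' @param dTEms echo-time difference (ms), default 1.02.
#' @param geom \linkS4class{ImageGeometry}; default 1 mm isotropic.
#' @param unwrapped TRUE for ground-truth/unwrapped fields beyond the
#'   Nyquist band.
#' @return a \linkS4class{FieldMap}.
#' @export
fieldMap <- function(offResonanceHz, mask = NULL, dTEms = 1.02, geom = NULL,
                     unwrapped = FALSE) {
  if (is.null(mask))
    mask <- matrix(TRUE, nrow(offResonanceHz), ncol(offResonanceHz))
  if (is.null(geom))
    geom <- imageGeometry(dim(offResonanceHz),
                          as.numeric(dim(offResonanceHz)), 1, "axial")
  new("FieldMap", offResonanceHz = offResonanceHz, mask = mask,
      dTEms = dTEms, unwrapped = unwrapped, geometry = geom)
}

#' Volume-selective shim solution
#'
#' Least-squares fit of a linear plus second-order spatial basis to a field
#' map over a region of interest, with pre/post residual statistics. For the
#' 2D (single-slice) case the z-dependent basis terms are dropped, leaving
#' \code{{offset, x, y, x^2 - y^2, xy}} with coordinates in mm relative to
#' the ROI centroid.
#'
#' @slot coefficients named numeric, Hz per mm (or mm^2) per basis term.
#' @slot order integer(1), 1 (linear) or 2.
#' @slot roi logical matrix.
#' @slot fittedHz numeric matrix, the fitted shim surface over the grid.
#' @slot stats named numeric: prePeakToPeakHz, postPeakToPeakHz, preRMSHz,
#'   postRMSHz over the ROI.
#' @export
setClass("ShimSolution",
  representation(coefficients = "numeric", order = "integer",
                 roi = "matrix", fittedHz = "matrix", stats = "numeric"))

setValidity("ShimSolution", function(object) {
  msg <- character(0)
  if (!object@order %in% 1:2) msg <- c(msg, "shim order must be 1 or 2")
  s <- object@stats
  if (all(c("prePeakToPeakHz", "postPeakToPeakHz") %in% names(s)) &&
      s["postPeakToPeakHz"] > s["prePeakToPeakHz"] + 1e-6)
    msg <- c(msg, "shim must not increase ROI peak-to-peak")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# T2StarMap
# ---------------------------------------------------------------------------

#' Per-voxel T2* fit results
#'
#' @slot t2StarMS 3D array (rows x cols x phases), fitted T2* in ms, NA
#'   outside the fitted mask.
#' @slot s0 3D array, fitted S0.
#' @slot status integer 3D array: 0 = converged, 1 = init retained
#'   (nonlinear stage failed), 2 = failed, 3 = clipped at a bound,
#'   NA outside mask.
#' @slot residual 3D array, residual norm of the reported fit.
#' @slot boundsMS numeric(2), (lower, upper] T2* bounds, default (0.1, 200].
#' @slot geometry \linkS4class{ImageGeometry}.
#' @export
setClass("T2StarMap",
  representation(t2StarMS = "array", s0 = "array", status = "array",
                 residual = "array", boundsMS = "numeric",
                 geometry = "ImageGeometry"))

setValidity("T2StarMap", function(object) {
  msg <- character(0)
  ok <- !is.na(object@t2StarMS)
  v <- object@t2StarMS[ok]
  if (length(v) && (any(v < object@boundsMS[1] - 1e-9) ||
                    any(v > object@boundsMS[2] + 1e-9)))
    msg <- c(msg, "fitted T2* outside configured bounds")
  if (!identical(dim(object@t2StarMS), dim(object@status)))
    msg <- c(msg, "status array must match map dimensions")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Registration classes
# ---------------------------------------------------------------------------

#' Paired 2D landmarks for one breath-hold
#'
#' Source points live in the image to be aligned (a breath-hold series);
#' target points are the matching locations in the reference. Coordinates
#' are 0-based voxel coordinates (x = column, y = row).
#'
#' @slot src numeric matrix (n x 2).
#' @slot dst numeric matrix (n x 2).
#' @slot hold integer(1), breath-hold index.
#' @export
setClass("LandmarkSet",
  representation(src = "matrix", dst = "matrix", hold = "integer"))

setValidity("LandmarkSet", function(object) {
  msg <- character(0)
  if (ncol(object@src) != 2L || ncol(object@dst) != 2L)
    msg <- c(msg, "landmark matrices must have two columns (x, y)")
  if (nrow(object@src) != nrow(object@dst))
    msg <- c(msg, "source and target lists must pair up")
  if (nrow(object@src) < 3L)
    msg <- c(msg, "a 2D affine needs at least 3 landmark pairs")
  if (length(msg)) msg else TRUE
})

#' 2D affine transform (linear part + translation)
#'
#' Maps source coordinates to target coordinates: y = A x + t, with x, y in
#' 0-based voxel coordinates (x = column, y = row).
#'
#' @slot A 2x2 numeric matrix, invertible.
#' @slot t numeric(2) translation.
#' @export
setClass("AffineTransform2D",
  representation(A = "matrix", t = "numeric"))

setValidity("AffineTransform2D", function(object) {
  msg <- character(0)
  if (!identical(dim(object@A), c(2L, 2L)))
    msg <- c(msg, "linear part must be 2x2")
  else if (abs(det(object@A)) < 1e-12)
    msg <- c(msg, "linear part must be invertible")
  if (length(object@t) != 2L) msg <- c(msg, "translation must be length 2")
  if (length(msg)) msg else TRUE
})

#' Construct a 2D affine transform
#' @param A 2x2 linear part.
#' @param t length-2 translation.
#' @return An \linkS4class{AffineTransform2D}.
#' @export
affineTransform2D <- function(A = diag(2), t = c(0, 0)) {
  new("AffineTransform2D", A = A, t = as.numeric(t))
}

# ---------------------------------------------------------------------------
# SegmentReport
# ---------------------------------------------------------------------------

#' Per-segment T2* statistics across the cardiac cycle
#'
#' @slot table data.frame, one row per (segment, phase): \code{segment},
#'   \code{phase}, \code{meanT2StarMS}, \code{sdT2StarMS}, \code{nVoxels},
#'   \code{flagged}.
#' @slot segmentSummary data.frame, one row per segment: end-diastolic and
#'   end-systolic means, cycle max/min, percent increase (max - min)/min.
#' @slot pairedTest named numeric: t statistic, p value, df for the paired
#'   end-diastole vs end-systole comparison across segments.
#' @slot endDiastolicPhase integer(1); phase of maximal cavity area.
#' @slot endSystolicPhase integer(1); phase of minimal cavity area.
#' @export
setClass("SegmentReport",
  representation(table = "data.frame", segmentSummary = "data.frame",
                 pairedTest = "numeric", endDiastolicPhase = "integer",
                 endSystolicPhase = "integer"))

setValidity("SegmentReport", function(object) {
  msg <- character(0)
  need <- c("segment", "phase", "meanT2StarMS", "sdT2StarMS", "nVoxels",
            "flagged")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table needs columns:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RunConfig
# ---------------------------------------------------------------------------

#' End-to-end pipeline run configuration
#'
#' Serializes losslessly to/from YAML via \code{\link{writeRunConfig}} and
#' \code{\link{readRunConfig}}; the seed is recorded in every output the
#' pipeline writes.
#'
#' @slot phantom list, phantom spec: \code{type} ("heart", "long", "medium")
#'   plus overrides passed to the generator.
#' @slot protocol list, \code{strategy} plus overrides passed to
#'   \code{\link{protocolPreset}}.
#' @slot noiseSigma numeric(1), receiver noise sd.
#' @slot seed integer(1).
#' @slot outDir character(1).
#' @export
setClass("RunConfig",
  representation(phantom = "list", protocol = "list", noiseSigma = "numeric",
                 seed = "integer", outDir = "character"))

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (is.null(object@phantom$type) ||
      !object@phantom$type %in% c("heart", "long", "medium"))
    msg <- c(msg, "phantom$type must be heart, long or medium")
  if (is.null(object@protocol$strategy))
    msg <- c(msg, "protocol$strategy is required")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#' @param phantom phantom spec list (needs \code{type}).
#' @param protocol protocol spec list (needs \code{strategy}).
#' @param noiseSigma receiver noise sd (arbitrary units).
#' @param seed integer random seed.
#' @param outDir output directory.
#' @return A \linkS4class{RunConfig}.
#' @export
runConfig <- function(phantom = list(type = "medium"),
                      protocol = list(strategy = "MS"),
                      noiseSigma = 0, seed = 1L, outDir = tempdir()) {
  new("RunConfig", phantom = phantom, protocol = protocol,
      noiseSigma = noiseSigma, seed = as.integer(seed), outDir = outDir)
}
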