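# Accessors and show methods. Slot access from user code is discouraged;
# these are the supported surface.

#' In-plane resolution in mm
#' @param x an \linkS4class{ImageGeometry} or object carrying one.
#' @return numeric(2), mm per voxel along (rows, columns).
#' @export
setGeneric("resolutionMM", function(x) standardGeneric("resolutionMM"))

#' @rdname resolutionMM
#' @export
setMethod("resolutionMM", "ImageGeometry", function(x) {
  x@fovMM / x@matrixSize
})

#' Geometry accessor
#' @param x an object with an image geometry.
#' @return the \linkS4class{ImageGeometry}.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname geometry
#' @export
setMethod("geometry", "TissueMap", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "EchoImageSeries", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "FieldMap", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "T2StarMap", function(x) x@geometry)

#' Number of cardiac phases
#' @param x a \linkS4class{TissueMap}, \linkS4class{EchoImageSeries} or
#'   \linkS4class{T2StarMap}.
#' @return integer(1).
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' @rdname nPhases
#' @export
setMethod("nPhases", "TissueMap", function(x) dim(x@S0)[3])
#' @rdname nPhases
#' @export
setMethod("nPhases", "EchoImageSeries",
          function(x) length(unique(x@frameInfo$phase)))
#' @rdname nPhases
#' @export
setMethod("nPhases", "T2StarMap", function(x) dim(x@t2StarMS)[3])

#' Frame metadata of an image series
#' @param x an \linkS4class{EchoImageSeries}.
#' @return data.frame with frame, echo, teMS, phase, hold.
#' @export
setGeneric("frameInfo", function(x) standardGeneric("frameInfo"))

#' @rdname frameInfo
#' @export
setMethod("frameInfo", "EchoImageSeries", function(x) x@frameInfo)

#' Complex, magnitude and phase data of an image series
#' @param x an \linkS4class{EchoImageSeries}.
#' @return \code{seriesData}: complex array; \code{magnitudeData}:
#'   non-negative array; \code{phaseData}: radians in [-pi, pi).
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))
#' @rdname seriesData
#' @export
setMethod("seriesData", "EchoImageSeries", function(x) x@data)

#' @rdname seriesData
#' @export
setGeneric("magnitudeData", function(x) standardGeneric("magnitudeData"))
#' @rdname seriesData
#' @export
setMethod("magnitudeData", "EchoImageSeries", function(x) Mod(x@data))

#' @rdname seriesData
#' @export
setGeneric("phaseData", function(x) standardGeneric("phaseData"))
#' @rdname seriesData
#' @export
setMethod("phaseData", "EchoImageSeries", function(x) wrapPhase(Arg(x@data)))

#' T2* values of a fitted map
#' @param x a \linkS4class{T2StarMap}.
#' @return 3D array in ms (NA outside the fitted mask).
#' @export
setGeneric("t2StarValues", function(x) standardGeneric("t2StarValues"))
#' @rdname t2StarValues
#' @export
setMethod("t2StarValues", "T2StarMap", function(x) x@t2StarMS)

#' Fit status codes of a T2* map
#' @param x a \linkS4class{T2StarMap}.
#' @return integer array: 0 converged, 1 init retained, 2 failed, 3 clipped.
#' @export
setGeneric("fitStatus", function(x) standardGeneric("fitStatus"))
#' @rdname fitStatus
#' @export
setMethod("fitStatus", "T2StarMap", function(x) x@status)

#' Off-resonance values of a field map
#' @param x a \linkS4class{FieldMap}.
#' @return numeric matrix in Hz.
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname fieldValues
#' @export
setMethod("fieldValues", "FieldMap", function(x) x@offResonanceHz)

#' Shim coefficients
#' @param object a \linkS4class{ShimSolution}.
#' @param ... unused.
#' @return named numeric vector (Hz/mm, Hz/mm^2; offset in Hz).
#' @export
setMethod("coef", "ShimSolution", function(object, ...) object@coefficients)

#' Shim residual statistics
#' @param x a \linkS4class{ShimSolution}.
#' @return named numeric: pre/post peak-to-peak and RMS over the ROI (Hz).
#' @export
setGeneric("shimStats", function(x) standardGeneric("shimStats"))
#' @rdname shimStats
#' @export
setMethod("shimStats", "ShimSolution", function(x) x@stats)

#' Segment report table accessor
#' @param x a \linkS4class{SegmentReport}.
#' @return data.frame with one row per (segment, cardiac phase).
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))
#' @rdname reportTable
#' @export
setMethod("reportTable", "SegmentReport", function(x) x@table)

#' Per-segment cycle summary accessor
#' @param x a \linkS4class{SegmentReport}.
#' @return data.frame with end-diastolic/end-systolic means, cycle max/min
#'   and percent increase per segment.
#' @export
setGeneric("segmentSummary", function(x) standardGeneric("segmentSummary"))
#' @rdname segmentSummary
#' @export
setMethod("segmentSummary", "SegmentReport", function(x) x@segmentSummary)

# ---- show methods ---------------------------------------------------------

setMethod("show", "ImageGeometry", function(object) {
  r <- resolutionMM(object)
  cat(sprintf("ImageGeometry: %d x %d, FOV (%g x %g) mm, res (%.3g x %.3g) mm, slice %g mm, %s\n",
              object@matrixSize[1], object@matrixSize[2],
              object@fovMM[1], object@fovMM[2], r[1], r[2],
              object@sliceThicknessMM, object@orientation))
})

setMethod("show", "TissueMap", function(object) {
  dm <- dim(object@S0)
  cat(sprintf("TissueMap: %d x %d voxels, %d cardiac phase(s)\n",
              dm[1], dm[2], dm[3]))
  inside <- object@S0[, , 1] > 0
  if (any(inside))
    cat(sprintf("  in-object T2* range %.1f - %.1f ms, |df| max %.1f Hz\n",
                min(object@T2StarMS[, , 1][inside]),
                max(object@T2StarMS[, , 1][inside]),
                max(abs(object@offResonanceHz))))
  show(object@geometry)
})

setMethod("show", "SequenceParams", function(object) {
  cat(sprintf("SequenceParams: %d echoes %.2f - %.2f ms, TR %.1f ms, flip %g deg, f0 %.1f MHz\n",
              length(object@teMS), min(object@teMS), max(object@teMS),
              object@trMS, object@flipDeg, object@f0MHz))
})

setMethod("show", "AcquisitionProtocol", function(object) {
  cat(sprintf("AcquisitionProtocol %s: %d lines, %d views/segment, %d excitation(s) x %d echo(es), TR %.1f ms, %d phase(s), %d breath-hold(s)\n",
              object@strategy, object@nLines, object@viewsPerSegment,
              object@nExcitations, object@echoesPerExcitation, object@trMS,
              object@nCardiacPhases, object@nBreathHolds))
  cat(sprintf("  scan duration %s, acquisition window %.0f ms\n",
              paste(format(scanDuration(object), digits = 3), "s"),
              acquisitionWindow(object)))
})

setMethod("show", "EchoImageSeries", function(object) {
  fi <- object@frameInfo
  cat(sprintf("EchoImageSeries (%s): %d frames = %d echo(es) x %d phase(s), %d breath-hold(s)\n",
              object@protocol, nrow(fi), length(unique(fi$echo)),
              length(unique(fi$phase)), length(unique(fi$hold))))
  show(object@geometry)
})

setMethod("show", "FieldMap", function(object) {
  v <- object@offResonanceHz[object@mask]
  cat(sprintf("FieldMap: dTE %.2f ms (Nyquist +-%.1f Hz), %d masked voxels",
              object@dTEms, 1000 / (2 * object@dTEms), sum(object@mask)))
  if (length(v))
    cat(sprintf(", range %.1f to %.1f Hz", min(v), max(v)))
  cat("\n")
})

setMethod("show", "ShimSolution", function(object) {
  s <- object@stats
  cat(sprintf("ShimSolution (order %d): peak-to-peak %.1f -> %.1f Hz, RMS %.1f -> %.1f Hz\n",
              object@order, s["prePeakToPeakHz"], s["postPeakToPeakHz"],
              s["preRMSHz"], s["postRMSHz"]))
})

setMethod("show", "T2StarMap", function(object) {
  ok <- !is.na(object@t2StarMS)
  cat(sprintf("T2StarMap: %d phase(s), %d fitted voxels/phase, bounds (%g, %g] ms\n",
              dim(object@t2StarMS)[3], sum(ok) / dim(object@t2StarMS)[3],
              object@boundsMS[1], object@boundsMS[2]))
  if (any(ok))
    cat(sprintf("  median T2* %.2f ms, %.1f%% voxels converged cleanly\n",
                stats::median(object@t2StarMS[ok]),
                100 * mean(object@status[ok] == 0L)))
})

setMethod("show", "AffineTransform2D", function(object) {
  cat("AffineTransform2D: y = A x + t\n")
  cat(sprintf("  A = [%.4f %.4f; %.4f %.4f], t = (%.3f, %.3f)\n",
              object@A[1, 1], object@A[1, 2], object@A[2, 1], object@A[2, 2],
              object@t[1], object@t[2]))
})

setMethod("show", "SegmentReport", function(object) {
  cat(sprintf("SegmentReport: %d segments x %d phases (ED phase %d, ES phase %d)\n",
              length(unique(object@table$segment)),
              length(unique(object@table$phase)),
              object@endDiastolicPhase, object@endSystolicPhase))
  if (nrow(object@segmentSummary)) {
    print(object@segmentSummary, digits = 3)
    if (!is.na(object@pairedTest["p"]))
      cat(sprintf("paired ED vs ES: t = %.3f, p = %.4g (df = %d)\n",
                  object@pairedTest["t"], object@pairedTest["p"],
                  as.integer(object@pairedTest["df"])))
  }
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: phantom %s, protocol %s, noise sigma %g, seed %d\n",
              object@phantom$type, object@protocol$strategy,
              object@noiseSigma, object@seed))
})
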