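# File I/O: NIfTI-1 volumes for image series and maps (magnitude and phase
# stored as separate volumes; phase in radians in [-pi, pi)), CSV sidecar
# tables for per-frame metadata, CSV segment reports, YAML run configs.

#' Write an echo image series to NIfTI volumes with a CSV sidecar
#'
#' Writes \code{<prefix>_mag.nii.gz} and \code{<prefix>_phase.nii.gz}
#' (rows x cols x frames; in-plane resolution and slice thickness in the
#' NIfTI pixdim) plus \code{<prefix>_frames.csv} with one row per frame:
#' frame, echo, teMS, phase (cardiac phase index), hold, orientation.
#'
#' @param series an \linkS4class{EchoImageSeries}.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
writeEchoSeries <- function(series, prefix) {
  g <- geometry(series)
  pd <- c(resolutionMM(g), g@sliceThicknessMM)
  mag <- RNifti::asNifti(magnitudeData(series))
  RNifti::pixdim(mag) <- pd
  ph <- RNifti::asNifti(phaseData(series))
  RNifti::pixdim(ph) <- pd
  RNifti::writeNifti(mag, paste0(prefix, "_mag.nii.gz"))
  RNifti::writeNifti(ph, paste0(prefix, "_phase.nii.gz"))
  fi <- frameInfo(series)
  fi$orientation <- g@orientation
  fi$protocol <- series@protocol
  utils::write.csv(fi, paste0(prefix, "_frames.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read an echo image series written by \code{\link{writeEchoSeries}}
#'
#' Magnitude and phase channels are paired back into complex frames; frame
#' metadata and geometry are restored from the sidecar and NIfTI header.
#'
#' @param prefix path prefix used when writing.
#' @return an \linkS4class{EchoImageSeries}.
#' @export
readImageSeries <- function(prefix) {
  magPath <- paste0(prefix, "_mag.nii.gz")
  phPath <- paste0(prefix, "_phase.nii.gz")
  sidecar <- paste0(prefix, "_frames.csv")
  if (!file.exists(magPath) || !file.exists(phPath))
    stop("format error: image volumes not found for prefix ", prefix)
  if (!file.exists(sidecar))
    stop("format error: missing sidecar table ", sidecar)
  mag <- RNifti::readNifti(magPath)
  ph <- RNifti::readNifti(phPath)
  fi <- utils::read.csv(sidecar)
  need <- c("frame", "echo", "teMS", "phase", "hold")
  if (!all(need %in% names(fi)))
    stop("format error: sidecar lacks columns ",
         paste(setdiff(need, names(fi)), collapse = ", "))
  dm <- dim(mag)
  if (length(dm) == 2L) dm <- c(dm, 1L)
  if (nrow(fi) != dm[3])
    stop(sprintf(
      "consistency error: sidecar lists %d frames but volume has %d",
      nrow(fi), dm[3]))
  pd <- RNifti::pixdim(mag)
  geom <- imageGeometry(dm[1:2], dm[1:2] * pd[1:2], pd[3],
                        orientation = if ("orientation" %in% names(fi))
                          fi$orientation[1] else "short-axis")
  dat <- array(complex(real = as.vector(mag) * cos(as.vector(ph)),
                       imaginary = as.vector(mag) * sin(as.vector(ph))), dm)
  newEchoImageSeries(dat, fi[, need],
                     geom, protocol = if ("protocol" %in% names(fi))
                       fi$protocol[1] else "none")
}

#' Write a T2* map (and fit status) as NIfTI volumes
#' @param t2map a \linkS4class{T2StarMap}.
#' @param prefix output path prefix; writes \code{<prefix>_t2star.nii.gz}
#'   (ms) and \code{<prefix>_status.nii.gz}.
#' @return the prefix, invisibly.
#' @export
writeT2StarMap <- function(t2map, prefix) {
  g <- geometry(t2map)
  pd <- c(resolutionMM(g), g@sliceThicknessMM)
  t2 <- RNifti::asNifti(t2StarValues(t2map))
  RNifti::pixdim(t2) <- pd
  RNifti::writeNifti(t2, paste0(prefix, "_t2star.nii.gz"))
  st <- fitStatus(t2map)
  st[is.na(st)] <- -1L
  st <- RNifti::asNifti(st)
  RNifti::pixdim(st) <- pd
  RNifti::writeNifti(st, paste0(prefix, "_status.nii.gz"))
  invisible(prefix)
}

#' Write a segment report as a delimited table
#'
#' One row per (segment, cardiac phase) with mean, standard deviation and
#' voxel count. Rows with an undefined mean (empty ROI) are written with the
#' flag set, never dropped.
#'
#' @param report a \linkS4class{SegmentReport}.
#' @param path output CSV path.
#' @param seed optional integer; when given, recorded in a \code{seed}
#'   column so every output carries its provenance.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path, seed = NULL) {
  tab <- reportTable(report)
  if (!nrow(tab)) stop("report is empty")
  if (!is.null(seed)) tab$seed <- as.integer(seed)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a run configuration (YAML)
#'
#' The round trip \code{readRunConfig(writeRunConfig(cfg, path))} is
#' lossless.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param path YAML file path.
#' @return \code{writeRunConfig}: the path; \code{readRunConfig}: a
#'   \linkS4class{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(list(phantom = config@phantom,
                        protocol = config@protocol,
                        noiseSigma = config@noiseSigma,
                        seed = config@seed, outDir = config@outDir), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  runConfig(phantom = x$phantom, protocol = x$protocol,
            noiseSigma = x$noiseSigma, seed = x$seed, outDir = x$outDir)
}
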