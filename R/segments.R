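# Mid-ventricular AHA segmentation (segments 7-12), ROI tracking across the
# cardiac cycle, per-segment T2* statistics and the paired end-diastole vs
# end-systole comparison.

#' AHA mid-ventricular segment labels
#'
#' Partitions an annulus-like myocardial mask into six 60-degree sectors
#' labeled 7-12 (anterior, anteroseptal, inferoseptal, inferior,
#' inferolateral, anterolateral). The sector angle is measured
#' counterclockwise on the displayed short-axis image (from anterior, i.e.
#' image top, toward the septal side) starting at the anterior RV-insertion
#' reference angle: a voxel at angle a gets label \code{7 + floor(((a -
#' insertion) mod 360) / 60)}.
#'
#' @param mask logical matrix, the myocardial mask (annulus-like, non-empty).
#' @param center length-2 (x, y) 0-based voxel coordinates of the cavity
#'   centre; default the mask centroid.
#' @param insertionAngleDeg anterior RV-insertion reference angle (degrees),
#'   default 0.
#' @return integer matrix: labels 7-12 inside the mask, NA outside, with
#'   attributes \code{center} and \code{insertionAngleDeg}.
#' @export
ahaSegments <- function(mask, center = NULL, insertionAngleDeg = 0) {
  if (!any(mask)) stop("myocardial mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(center))
    center <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)  # (x, y), 0-based
  dx <- (idx[, 2] - 1) - center[1]
  dy <- (idx[, 1] - 1) - center[2]
  ang <- ccwAngleDeg(dx, dy)
  lab <- 7L + as.integer(floor(((ang - insertionAngleDeg) %% 360) / 60))
  out <- matrix(NA_integer_, nrow(mask), ncol(mask))
  out[idx] <- lab
  attr(out, "center") <- center
  attr(out, "insertionAngleDeg") <- insertionAngleDeg
  out
}

#' Track the segmental ROI across the cardiac cycle
#'
#' Re-derives the six sectors at every cardiac phase from that phase's
#' myocardial mask and centre, so that only compact myocardium is included
#' as the wall contracts; blood-pool voxels are never labeled.
#'
#' @param masks logical array (rows x cols x phases) of per-phase myocardial
#'   masks (generator truth or user input).
#' @param insertionAngleDeg anterior RV-insertion reference angle.
#' @param centers optional phases x 2 matrix of (x, y) centres; default the
#'   per-phase mask centroid.
#' @param erodeVox morphological erosion (in voxels) applied to each mask
#'   before labeling, restricting the ROI to compact myocardium away from
#'   the endo- and epicardial borders so blood-pool and boundary
#'   partial-volume voxels are excluded. Default 1.
#' @return integer array of per-phase labels (NA outside the mask). Phases
#'   with an empty (post-erosion) mask yield all-NA labels and are listed in
#'   the \code{emptyPhases} attribute.
#' @export
trackROI <- function(masks, insertionAngleDeg = 0, centers = NULL,
                     erodeVox = 1L) {
  nP <- dim(masks)[3]
  out <- array(NA_integer_, dim(masks))
  empty <- integer(0)
  for (p in seq_len(nP)) {
    m <- masks[, , p]
    for (k in seq_len(erodeVox)) m <- erodeMask(m)
    if (!any(m)) { empty <- c(empty, p); next }
    ctr <- if (is.null(centers)) NULL else centers[p, ]
    out[, , p] <- ahaSegments(m, center = ctr,
                              insertionAngleDeg = insertionAngleDeg)
  }
  attr(out, "emptyPhases") <- empty
  out
}

# binary erosion with the 4-connected cross structuring element
erodeMask <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -nc, drop = FALSE])
  m & up & dn & lf & rt
}

#' Per-segment T2* statistics across the cardiac cycle
#'
#' Mean, standard deviation and voxel count of fitted T2* per (segment,
#' cardiac phase); end-diastolic/end-systolic values at the configured
#' phases; per-segment cycle maximum, minimum and percent increase
#' \code{(max - min)/min}; and the paired end-diastole vs end-systole
#' comparison across segments. Segments with fewer than \code{minVoxels}
#' fitted voxels in a phase are flagged (their row is kept, never dropped).
#'
#' @param t2map a \linkS4class{T2StarMap}.
#' @param labels integer array of per-phase segment labels (from
#'   \code{\link{trackROI}}), sharing the map's geometry; a single matrix is
#'   reused for every phase.
#' @param edPhase,esPhase end-diastolic / end-systolic phase indices. If
#'   NULL and \code{cavityAreaVox} is given, they are taken as the phases of
#'   maximal / minimal cavity area; otherwise default to 1 and the phase
#'   with the smallest mean T2* (the systolic minimum).
#' @param cavityAreaVox optional per-phase cavity areas (generator truth).
#' @param minVoxels minimum voxels for an unflagged mean, default 10.
#' @return a \linkS4class{SegmentReport}.
#' @export
segmentStats <- function(t2map, labels, edPhase = NULL, esPhase = NULL,
                         cavityAreaVox = NULL, minVoxels = 10L) {
  t2 <- t2StarValues(t2map)
  nP <- dim(t2)[3]
  if (is.matrix(labels)) labels <- array(labels, dim(t2))
  if (!identical(dim(labels)[1:2], dim(t2)[1:2]))
    stop("labels and map must share geometry")
  if (dim(labels)[3] != nP)
    stop("labels must cover every cardiac phase")
  segs <- 7:12
  tab <- expand.grid(segment = segs, phase = seq_len(nP))
  tab$meanT2StarMS <- NA_real_; tab$sdT2StarMS <- NA_real_
  tab$nVoxels <- 0L; tab$flagged <- FALSE
  for (r in seq_len(nrow(tab))) {
    p <- tab$phase[r]
    v <- t2[, , p][which(labels[, , p] == tab$segment[r])]
    v <- v[!is.na(v)]
    tab$nVoxels[r] <- length(v)
    if (length(v)) {
      tab$meanT2StarMS[r] <- mean(v)
      tab$sdT2StarMS[r] <- stats::sd(v)
    }
    tab$flagged[r] <- length(v) < minVoxels || !is.finite(tab$meanT2StarMS[r])
  }
  if (is.null(edPhase))
    edPhase <- if (!is.null(cavityAreaVox)) which.max(cavityAreaVox) else 1L
  if (is.null(esPhase))
    esPhase <- if (!is.null(cavityAreaVox)) which.min(cavityAreaVox) else {
      pm <- vapply(seq_len(nP), function(p)
        mean(tab$meanT2StarMS[tab$phase == p], na.rm = TRUE), 0)
      which.min(pm)
    }
  m <- matrix(tab$meanT2StarMS, nrow = length(segs))  # segs x phases
  rng <- function(f) apply(m, 1, function(v)
    if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE))
  summary <- data.frame(
    segment = segs,
    endDiastolicMS = m[, edPhase],
    endSystolicMS = m[, esPhase],
    cycleMaxMS = rng(max),
    cycleMinMS = rng(min))
  summary$percentIncrease <-
    100 * (summary$cycleMaxMS - summary$cycleMinMS) / summary$cycleMinMS
  pt <- pairedComparison(summary$endDiastolicMS, summary$endSystolicMS)
  new("SegmentReport", table = tab, segmentSummary = summary,
      pairedTest = c(t = pt$t, p = pt$p, df = pt$df),
      endDiastolicPhase = as.integer(edPhase),
      endSystolicPhase = as.integer(esPhase))
}

#' Paired two-sided t-test from its closed form
#'
#' \code{t = mean(d) / (sd(d)/sqrt(n))} for paired differences \code{d},
#' with n - 1 degrees of freedom; the two-sided p-value comes from the t
#' distribution CDF. Zero variance of the differences is degenerate and
#' flagged (identical vectors report t = 0, p = 1).
#'
#' @param x,y equal-length paired samples, n >= 2.
#' @return list: \code{t}, \code{p}, \code{df}, \code{meanDiff},
#'   \code{degenerate}.
#' @examples
#' pairedComparison(c(2, 3, 4), c(1, 1, 1))  # t = 2 sqrt(3), p ~ 0.0742
#' @export
pairedComparison <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2L) stop("need at least two pairs")
  sdd <- stats::sd(d)
  md <- mean(d)
  if (sdd == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    return(list(t = t, p = if (md == 0) 1 else 0, df = n - 1L,
                meanDiff = md, degenerate = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1),
       df = n - 1L, meanDiff = md, degenerate = FALSE)
}
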