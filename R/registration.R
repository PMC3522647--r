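# Landmark-based affine (shift + shear) registration used to align the
# multiple breath-hold series of MB CINE before voxelwise fitting.
# Coordinates are 0-based voxel coordinates (x = column, y = row).

#' Construct a landmark set
#' @param src n x 2 matrix of (x, y) points in the image to align.
#' @param dst n x 2 matrix of matching points in the reference.
#' @param hold breath-hold index, default 1.
#' @return a \linkS4class{LandmarkSet}.
#' @export
landmarkSet <- function(src, dst, hold = 1L) {
  new("LandmarkSet", src = as.matrix(src), dst = as.matrix(dst),
      hold = as.integer(hold))
}

#' Estimate a 2D affine transform from paired landmarks
#'
#' Least-squares affine minimizing the landmark residual; exact for three
#' non-collinear pairs. The returned transform maps source (breath-hold)
#' coordinates to target (reference) coordinates. A restriction can confine
#' the estimate to the stated transform class.
#'
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param restriction "affine" (default: full shift + shear + scale class),
#'   "translation" (shift only), or "shear" (unit-diagonal linear part).
#' @return an \linkS4class{AffineTransform2D}.
#' @export
estimateAffine <- function(landmarks, restriction = c("affine",
                                                      "translation",
                                                      "shear")) {
  restriction <- match.arg(restriction)
  src <- landmarks@src; dst <- landmarks@dst
  if (restriction == "translation")
    return(affineTransform2D(diag(2), colMeans(dst - src)))
  X <- cbind(src, 1)
  if (qr(cbind(src[, 1] - mean(src[, 1]), src[, 2] - mean(src[, 2])))$rank < 2L)
    stop("landmarks are collinear; affine is rank-deficient")
  beta <- qr.coef(qr(X), dst)          # 3 x 2: rows = (x, y, 1) weights
  A <- t(beta[1:2, ])
  tvec <- as.numeric(beta[3, ])
  if (restriction == "shear") {
    # re-solve with unit diagonal: dst - src = shear terms + translation
    d <- dst - src
    bx <- qr.coef(qr(cbind(src[, 2], 1)), d[, 1])  # x' - x = a12 y + tx
    by <- qr.coef(qr(cbind(src[, 1], 1)), d[, 2])  # y' - y = a21 x + ty
    A <- matrix(c(1, by[1], bx[1], 1), 2, 2)
    tvec <- c(bx[2], by[2])
  }
  affineTransform2D(A, tvec)
}

#' Compose and invert affine transforms
#' @param tf,tf2 \linkS4class{AffineTransform2D} objects.
#' @return \code{invertAffine}: the inverse transform;
#'   \code{composeAffine}: the transform applying \code{tf2} after
#'   \code{tf}.
#' @export
invertAffine <- function(tf) {
  Ainv <- solve(tf@A)
  affineTransform2D(Ainv, -drop(Ainv %*% tf@t))
}

#' @rdname invertAffine
#' @export
composeAffine <- function(tf2, tf) {
  affineTransform2D(tf2@A %*% tf@A, drop(tf2@A %*% tf@t) + tf2@t)
}

#' Map points through an affine transform
#' @param tf an \linkS4class{AffineTransform2D}.
#' @param pts n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
transformPoints <- function(tf, pts) {
  pts <- matrix(pts, ncol = 2)
  sweep(pts %*% t(tf@A), 2, tf@t, `+`)
}

# Resample one image under a forward transform: the output at coordinate y
# takes the input value at T^{-1}(y), bilinear interpolation, out-of-field
# voxels set to `outside`.
warpImage <- function(img, tf, outside = 0) {
  nr <- nrow(img); nc <- ncol(img)
  inv <- invertAffine(tf)
  grid <- cbind(x = rep(0:(nc - 1), each = nr), y = rep(0:(nr - 1), nc))
  srcPts <- transformPoints(inv, grid)
  sx <- srcPts[, 1]; sy <- srcPts[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(yy, xx) {
    ok <- xx >= 0 & xx <= nc - 1 & yy >= 0 & yy <= nr - 1
    out <- rep(outside, length(xx))
    out[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    out
  }
  v <- (1 - fx) * (1 - fy) * val(y0, x0) +
    fx * (1 - fy) * val(y0, x0 + 1) +
    (1 - fx) * fy * val(y0 + 1, x0) +
    fx * fy * val(y0 + 1, x0 + 1)
  matrix(v, nr, nc)
}

#' Apply an affine transform to an image or image series
#'
#' Resamples with bilinear interpolation (real and imaginary channels
#' separately for complex data); voxels mapped from outside the field of
#' view are set to 0.
#'
#' @param x a numeric matrix, complex matrix, or
#'   \linkS4class{EchoImageSeries}.
#' @param tf an \linkS4class{AffineTransform2D} (must be invertible).
#' @return object of the same type, resampled.
#' @export
applyTransform <- function(x, tf) {
  validObject(tf)
  if (is(x, "EchoImageSeries")) {
    dat <- seriesData(x)
    out <- dat
    for (f in seq_len(dim(dat)[3]))
      out[, , f] <- complex(real = warpImage(Re(dat[, , f]), tf),
                            imaginary = warpImage(Im(dat[, , f]), tf))
    return(newEchoImageSeries(out, frameInfo(x), geometry(x), x@protocol))
  }
  if (is.complex(x))
    return(complex(real = warpImage(Re(x), tf),
                   imaginary = warpImage(Im(x), tf)) |>
             matrix(nrow(x), ncol(x)))
  warpImage(x, tf)
}

#' Landmarks induced by a known ground-truth perturbation
#'
#' For simulation fixtures: given the transform that displaced a breath-hold
#' (reference -> hold coordinates), returns the landmark set a reader would
#' annotate — reference positions as targets and their displaced positions
#' as sources.
#'
#' @param tf the applied \linkS4class{AffineTransform2D}.
#' @param refPts n x 2 matrix of reference (x, y) voxel coordinates.
#' @param hold breath-hold index.
#' @return a \linkS4class{LandmarkSet}.
#' @export
landmarksFromTransform <- function(tf, refPts, hold = 1L) {
  landmarkSet(src = transformPoints(tf, refPts), dst = refPts, hold = hold)
}

#' Residual alignment error after registration
#'
#' Composes the estimated correction with the applied perturbation and
#' reports the largest displacement from identity over a set of points.
#'
#' @param applied the ground-truth perturbation (reference -> hold).
#' @param estimated the estimated correction (hold -> reference).
#' @param pts n x 2 matrix of evaluation points (voxel coordinates).
#' @return maximum residual displacement in voxels.
#' @export
alignmentError <- function(applied, estimated, pts) {
  comp <- composeAffine(estimated, applied)
  max(sqrt(rowSums((transformPoints(comp, pts) - pts)^2)))
}

#' Register the breath-holds of an MB CINE acquisition
#'
#' Estimates one affine per breath-hold from its landmark set and resamples
#' every frame of that hold, returning a merged series ready for
#' \code{\link{mapFit}}.
#'
#' @param seriesList list of single-hold \linkS4class{EchoImageSeries}
#'   (from \code{\link{splitByHold}}).
#' @param landmarkSets list of \linkS4class{LandmarkSet}, one per hold.
#' @param restriction transform class, see \code{\link{estimateAffine}}.
#' @return list: \code{series} (merged \linkS4class{EchoImageSeries}),
#'   \code{transforms} (per-hold estimates).
#' @export
registerBreathHolds <- function(seriesList, landmarkSets,
                                restriction = "affine") {
  if (length(seriesList) != length(landmarkSets))
    stop("need one landmark set per breath-hold series")
  tfs <- lapply(landmarkSets, estimateAffine, restriction = restriction)
  aligned <- mapply(function(s, tf) applyTransform(s, tf),
                    seriesList, tfs, SIMPLIFY = FALSE)
  list(series = mergeBreathHolds(aligned), transforms = tfs)
}

#' Read and write landmark CSV files
#'
#' Columns: \code{hold, x_src, y_src, x_dst, y_dst} (0-based voxel
#' coordinates).
#'
#' @param path CSV file path.
#' @return \code{readLandmarks}: list of \linkS4class{LandmarkSet} by hold.
#' @export
readLandmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("hold", "x_src", "y_src", "x_dst", "y_dst")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$hold), function(d)
    landmarkSet(cbind(d$x_src, d$y_src), cbind(d$x_dst, d$y_dst),
                hold = d$hold[1]))
}

#' @rdname readLandmarks
#' @param landmarkSets list of \linkS4class{LandmarkSet}.
#' @export
writeLandmarks <- function(landmarkSets, path) {
  df <- do.call(rbind, lapply(landmarkSets, function(l)
    data.frame(hold = l@hold, x_src = l@src[, 1], y_src = l@src[, 2],
               x_dst = l@dst[, 1], y_dst = l@dst[, 2])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
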