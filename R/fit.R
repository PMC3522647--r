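# Per-voxel T2* estimation: log-linear initialization followed by bounded
# mono-exponential nonlinear least squares S(TE) = S0 exp(-TE / T2*) on
# magnitude data, with quality masking. Failed voxels are flagged, never
# silently interpolated.

#' Log-linear initialization of the mono-exponential fit
#'
#' Ordinary least squares of \code{ln S} on TE over the strictly positive
#' samples: T2* = -1/slope. Following the estimation rule that S0 is taken
#' from the sample at the minimum echo time, \code{s0} is \code{S(TEmin)}
#' (not the log-linear intercept) — the two differ by the decay over TEmin;
#' the intercept-based value is returned as \code{s0Intercept}.
#'
#' @param signal magnitude samples.
#' @param teMS echo times (ms), strictly increasing.
#' @param boundsMS T2* bounds (ms); degenerate (flat or growing) decays clip
#'   to the upper bound and are flagged.
#' @return list: \code{s0}, \code{t2StarMS}, \code{s0Intercept},
#'   \code{ok} (logical), \code{clipped} (logical).
#' @examples
#' loglinearInit(c(100, 90), c(2.04, 3.06))$t2StarMS  # 1.02/log(100/90)
#' @export
loglinearInit <- function(signal, teMS, boundsMS = c(0.1, 200)) {
  if (length(signal) != length(teMS) || length(signal) < 2L)
    stop("need >= 2 samples with matching echo times")
  if (any(diff(teMS) <= 0)) stop("echo times must be strictly increasing")
  pos <- signal > 0
  if (sum(pos) < 2L)
    return(list(s0 = NA_real_, t2StarMS = NA_real_,
                s0Intercept = NA_real_, ok = FALSE, clipped = FALSE))
  te <- teMS[pos]; ls <- log(signal[pos])
  teC <- te - mean(te)
  slope <- sum(teC * ls) / sum(teC^2)
  intercept <- mean(ls) - slope * mean(te)
  clipped <- FALSE
  if (slope >= -1 / boundsMS[2]) {        # flat or growing: T2* -> upper bound
    t2 <- boundsMS[2]; clipped <- TRUE
  } else if (slope < -1 / boundsMS[1]) {  # implausibly fast decay
    t2 <- boundsMS[1]; clipped <- TRUE
  } else t2 <- -1 / slope
  list(s0 = signal[which.min(teMS)], t2StarMS = t2,
       s0Intercept = exp(intercept), ok = TRUE, clipped = clipped)
}

#' Bounded mono-exponential nonlinear fit
#'
#' Nonlinear least squares of \code{S(TE) = S0 exp(-TE/T2*)} on magnitude
#' samples via bounded Levenberg-Marquardt, initialized from
#' \code{\link{loglinearInit}} values. T2* is constrained to
#' \code{boundsMS}; on non-convergence, or if the optimizer fails to improve
#' on the initialization, the initialization is retained and flagged.
#'
#' @param signal magnitude samples (all samples enter the nonlinear stage;
#'   only the log stage excludes non-positive values).
#' @param teMS echo times (ms).
#' @param init list from \code{\link{loglinearInit}}; computed when NULL.
#' @param boundsMS T2* bounds, default (0.1, 200] ms.
#' @return list: \code{s0}, \code{t2StarMS}, \code{residual} (L2 norm),
#'   \code{status} (0 converged, 1 init retained, 2 failed, 3 at a bound).
#' @export
fitMonoexp <- function(signal, teMS, init = NULL, boundsMS = c(0.1, 200)) {
  if (is.null(init)) init <- loglinearInit(signal, teMS, boundsMS)
  if (!isTRUE(init$ok))
    return(list(s0 = NA_real_, t2StarMS = NA_real_, residual = NA_real_,
                status = 2L))
  model <- function(p) p[1] * exp(-teMS / p[2])
  residFun <- function(p) signal - model(p)
  p0 <- c(max(init$s0, 1e-12), init$t2StarMS)
  initResid <- sqrt(sum(residFun(p0)^2))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = residFun,
                       lower = c(0, boundsMS[1]),
                       upper = c(Inf, boundsMS[2]),
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(s0 = init$s0, t2StarMS = init$t2StarMS,
                residual = initResid, status = 1L))
  resid <- sqrt(sum(residFun(fit$par)^2))
  if (!is.finite(resid) || resid > initResid + 1e-12)
    return(list(s0 = init$s0, t2StarMS = init$t2StarMS,
                residual = initResid, status = 1L))
  atBound <- fit$par[2] <= boundsMS[1] + 1e-9 ||
    fit$par[2] >= boundsMS[2] - 1e-9
  list(s0 = fit$par[1], t2StarMS = fit$par[2], residual = resid,
       status = if (atBound) 3L else 0L)
}

#' Voxelwise T2* mapping of an image series
#'
#' Applies \code{\link{loglinearInit}} + \code{\link{fitMonoexp}} to the
#' magnitude decay of every voxel inside the mask, one map per cardiac
#' phase. All breath-holds present in the series contribute their echoes
#' (register and \code{\link{mergeBreathHolds}} first for multi-breath-hold
#' data).
#'
#' @param series an \linkS4class{EchoImageSeries}.
#' @param mask logical matrix (voxels to fit), non-empty; or a rows x cols x
#'   phases logical array for phase-dependent masks.
#' @param minEchoes minimum echoes required, default 3.
#' @param boundsMS T2* bounds, default (0.1, 200] ms.
#' @return a \linkS4class{T2StarMap}.
#' @export
mapFit <- function(series, mask, minEchoes = 3L, boundsMS = c(0.1, 200)) {
  fi <- frameInfo(series)
  phases <- sort(unique(fi$phase))
  geom <- geometry(series)
  dm <- c(geom@matrixSize, length(phases))
  if (is.matrix(mask)) mask <- array(mask, dm)
  if (!any(mask)) stop("mask is empty")
  mag <- magnitudeData(series)
  t2 <- array(NA_real_, dm); s0 <- array(NA_real_, dm)
  st <- array(NA_integer_, dm); rs <- array(NA_real_, dm)
  for (pi in seq_along(phases)) {
    sel <- fi[fi$phase == phases[pi], ]
    sel <- sel[order(sel$teMS), ]
    if (nrow(sel) < minEchoes)
      stop(sprintf("phase %d has %d echoes; %d required", phases[pi],
                   nrow(sel), minEchoes))
    te <- sel$teMS
    idx <- which(mask[, , pi])
    if (!length(idx)) next
    sig <- matrix(0, length(idx), length(te))
    for (k in seq_along(sel$frame))
      sig[, k] <- mag[, , sel$frame[k]][idx]
    for (v in seq_along(idx)) {
      f <- fitMonoexp(sig[v, ], te, boundsMS = boundsMS)
      i2 <- idx[v] + (pi - 1) * dm[1] * dm[2]
      t2[i2] <- f$t2StarMS; s0[i2] <- f$s0
      st[i2] <- f$status; rs[i2] <- f$residual
    }
  }
  new("T2StarMap", t2StarMS = t2, s0 = s0, status = st, residual = rs,
      boundsMS = boundsMS, geometry = geom)
}
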