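# Voxel-level spoiled gradient-echo signal physics: mono-exponential T2*
# decay, intravoxel dephasing under a linear-phase (sinc) model, fat-water
# phase evolution, optional T1 steady-state weighting, complex Gaussian
# receiver noise.

#' Wrap phase to [-pi, pi)
#' @param phi phase in radians.
#' @return wrapped phase.
#' @export
wrapPhase <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}

#' Arithmetic echo schedule
#'
#' @param teMinMS first echo time (ms).
#' @param dTEms inter-echo spacing (ms).
#' @param nEchoes number of echoes.
#' @return numeric vector \code{teMinMS + (0:(n-1)) * dTEms}.
#' @examples
#' echoSchedule(2.04, 1.02, 9)   # 2.04 ... 10.20 ms
#' echoSchedule(2.04, 3.06, 6)   # the 6-echo variant
#' @export
echoSchedule <- function(teMinMS, dTEms, nEchoes) {
  if (nEchoes <= 0) stop("nEchoes must be positive")
  if (teMinMS <= 0 || dTEms <= 0) stop("echo timing must be positive")
  teMinMS + (seq_len(nEchoes) - 1) * dTEms
}

#' Fat-water in-phase echo spacing
#'
#' The echo-time increment at which fat and water magnetizations realign:
#' the reciprocal of the chemical-shift frequency difference
#' \code{f0 * shift}. At 297.2 MHz (7 T) and 3.3 ppm this is 1.02 ms.
#'
#' @param f0MHz proton resonance frequency (MHz).
#' @param shiftPPM fat-water chemical shift (ppm).
#' @return spacing in ms.
#' @examples
#' round(fatWaterInPhaseSpacing(297.2, 3.3), 2)  # 1.02
#' @export
fatWaterInPhaseSpacing <- function(f0MHz, shiftPPM) {
  if (f0MHz <= 0) stop("f0 must be positive")
  if (shiftPPM <= 0) stop("chemical shift must be positive (undefined at 0)")
  1000 / (f0MHz * shiftPPM)  # 1 / (f0e6 * ppm*1e-6) s -> ms
}

#' Intravoxel dephasing amplitude factor (linear-phase sinc model)
#'
#' For a voxel spanning a uniform frequency dispersion of \code{dispersionHz}
#' (total spread across the voxel extent), the net magnitude attenuation at
#' echo time TE is \code{|sin(pi x) / (pi x)|} with \code{x = dispersion[kHz]
#' * TE[ms]}; 1 at zero dispersion.
#'
#' @param dispersionHz total frequency spread across the voxel (Hz), >= 0.
#' @param teMS echo time(s) in ms.
#' @return attenuation factor(s) in [0, 1]. Inputs are recycled.
#' @examples
#' dephasingFactor(100, 5)   # 2/pi
#' dephasingFactor(80, 10)   # ~0.234: ~77% signal loss
#' @export
dephasingFactor <- function(dispersionHz, teMS) {
  if (any(dispersionHz < 0)) stop("dispersion must be non-negative")
  x <- (dispersionHz / 1000) * teMS
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- abs(sin(pi * x[nz]) / (pi * x[nz]))
  out
}

#' Steady-state (T1 saturation) amplitude factor of a spoiled gradient echo
#'
#' \code{sin(a) (1 - E1) / (1 - cos(a) E1)} with \code{E1 = exp(-TR/T1)}.
#' Off (factor 1) when T1 is NA, the default throughout, because the
#' mono-exponential decay model absorbs any TE-independent scale.
#'
#' @param flipDeg flip angle in degrees.
#' @param trMS repetition time (ms).
#' @param t1MS longitudinal relaxation time (ms) or NA.
#' @return scalar factor.
#' @export
steadyStateFactor <- function(flipDeg, trMS, t1MS = NA_real_) {
  if (is.na(t1MS)) return(1)
  a <- flipDeg * pi / 180
  e1 <- exp(-trMS / t1MS)
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Complex spoiled gradient-echo signal of one voxel
#'
#' Magnitude: \code{S0 * steadyStateFactor * exp(-TE/T2*) * dephasing * |fat
#' modulation|}; phase: \code{2 pi df TE} plus the fat component's phase.
#' Fat is modeled as a single resonance at the configured ppm shift.
#' Dispersions along the two in-plane axes and the through-plane axis are
#' applied as independent sinc factors (multiplicatively).
#'
#' @param s0 equilibrium signal (arbitrary units).
#' @param t2StarMS T2* in ms (> 0).
#' @param teMS echo time(s) in ms (> 0).
#' @param offResonanceHz frequency offset in Hz.
#' @param dispersionHz total intravoxel dispersion per axis, a numeric vector
#'   (any length, each axis contributing one sinc factor); default 0.
#' @param fatFraction fat fraction in [0, 1], default 0.
#' @param seq a \linkS4class{SequenceParams} supplying flip angle, TR, f0,
#'   fat shift and T1; default \code{sequenceParams()}.
#' @return complex signal, vectorized over \code{teMS}.
#' @examples
#' Mod(greSignal(100, 20, 2.04))  # 100 * exp(-0.102) ~ 90.3
#' @export
greSignal <- function(s0, t2StarMS, teMS, offResonanceHz = 0,
                      dispersionHz = 0, fatFraction = 0,
                      seq = sequenceParams()) {
  if (any(teMS <= 0)) stop("TE must be positive")
  if (t2StarMS <= 0) stop("T2* must be positive")
  deph <- rep(1, length(teMS))
  for (d in dispersionHz) deph <- deph * dephasingFactor(d, teMS)
  fatHz <- seq@f0MHz * seq@fatShiftPPM  # chemical-shift frequency in Hz
  fat <- (1 - fatFraction) + fatFraction * exp(1i * 2 * pi * fatHz * teMS / 1000)
  ss <- steadyStateFactor(seq@flipDeg, seq@trMS, seq@t1MS)
  s0 * ss * exp(-teMS / t2StarMS) * deph * fat *
    exp(1i * 2 * pi * offResonanceHz * teMS / 1000)
}

#' Add complex Gaussian receiver noise
#'
#' Independent zero-mean Gaussian noise of standard deviation \code{sigma}
#' is added to the real and imaginary channels, making the magnitude
#' Rician-distributed.
#'
#' @param img complex array or matrix.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed; NA leaves the RNG stream untouched.
#' @return complex array of the same shape.
#' @export
addNoise <- function(img, sigma, seed = NA_integer_) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(img)
  if (!is.na(seed)) set.seed(as.integer(seed))
  n <- length(img)
  img + complex(real = stats::rnorm(n, 0, sigma),
                imaginary = stats::rnorm(n, 0, sigma))
}

# ---------------------------------------------------------------------------
# Whole-image rendering (internal; used by the acquisition engine)
# ---------------------------------------------------------------------------

# In-plane off-resonance gradients (Hz/mm) by central/one-sided finite
# differences, per cardiac phase frame.
inPlaneGradients <- function(df, resMM) {
  nr <- nrow(df); nc <- ncol(df)
  gr <- matrix(0, nr, nc)  # along rows
  gc <- matrix(0, nr, nc)  # along columns
  if (nr > 1) {
    gr[2:(nr - 1), ] <- (df[3:nr, ] - df[1:(nr - 2), ]) / (2 * resMM[1])
    gr[1, ] <- (df[2, ] - df[1, ]) / resMM[1]
    gr[nr, ] <- (df[nr, ] - df[nr - 1, ]) / resMM[1]
  }
  if (nc > 1) {
    gc[, 2:(nc - 1)] <- (df[, 3:nc] - df[, 1:(nc - 2)]) / (2 * resMM[2])
    gc[, 1] <- (df[, 2] - df[, 1]) / resMM[2]
    gc[, nc] <- (df[, nc] - df[, nc - 1]) / resMM[2]
  }
  list(rows = gr, cols = gc)
}

# Render the complex image of one phantom frame at one echo time.
# Through-plane dispersion = |dF/dz| * slice thickness; in-plane dispersion =
# |in-plane gradient| * voxel extent; the three sinc factors multiply.
renderEchoImage <- function(tissue, frameIdx, teMS, seq) {
  g <- tissue@geometry
  res <- resolutionMM(g)
  s0 <- tissue@S0[, , frameIdx]
  t2 <- tissue@T2StarMS[, , frameIdx]
  df <- tissue@offResonanceHz[, , frameIdx]
  ff <- tissue@fatFraction[, , frameIdx]
  dz <- abs(tissue@dFdzHzPerMM[, , frameIdx]) * g@sliceThicknessMM
  gr <- inPlaneGradients(df, res)
  dx <- abs(gr$rows) * res[1]
  dy <- abs(gr$cols) * res[2]
  inside <- s0 > 0
  t2safe <- ifelse(inside, t2, 1)  # decay irrelevant where S0 = 0
  deph <- dephasingFactor(as.vector(dz), teMS) *
    dephasingFactor(as.vector(dx), teMS) *
    dephasingFactor(as.vector(dy), teMS)
  fatHz <- seq@f0MHz * seq@fatShiftPPM
  fat <- (1 - ff) + ff * exp(1i * 2 * pi * fatHz * teMS / 1000)
  ss <- steadyStateFactor(seq@flipDeg, seq@trMS, seq@t1MS)
  img <- s0 * ss * exp(-teMS / t2safe) * matrix(deph, nrow(s0), ncol(s0)) *
    fat * exp(1i * 2 * pi * df * teMS / 1000)
  img[!inside] <- 0 + 0i
  img
}
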