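## Persistence-length estimation from filament shapes (Gittes-style): tangent
## angles are decomposed on a free-end cosine basis; for a 2-D worm-like chain
## the ensemble variance of the mode amplitudes follows
## var(a(q)) = (1/Lp) * (1/q^2) with q_n = n*pi/L, and Lp is recovered by an
## inverse-square-law fit. The amplitude normalization sqrt(2/L) is fixed so
## that exactly this law holds.

#' Resample a filament and compute unwrapped tangent angles
#'
#' The polyline is resampled at uniform arclength spacing; tangent angles are
#' the segment angles, unwrapped, and are located at segment midpoints.
#'
#' @param points two-column matrix or data.frame of ordered (x, y) positions
#'   (um); >= 8 points, no duplicate consecutive points.
#' @param resampleStep target arclength step (um); defaults to the mean
#'   original spacing.
#' @return a [FilamentShape-class].
#' @export
tangentAngles <- function(points, resampleStep = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) < 2L) stop("'points' needs x and y columns")
  pts <- pts[, 1:2, drop = FALSE]
  if (nrow(pts) < 8L) stop("need at least 8 points per filament")
  seg <- diff(pts)
  segLen <- sqrt(rowSums(seg^2))
  if (any(segLen == 0)) stop("duplicate consecutive points")
  sOrig <- c(0, cumsum(segLen))
  L0 <- sOrig[length(sOrig)]
  if (is.null(resampleStep)) resampleStep <- L0 / (nrow(pts) - 1L)
  assertScalar(resampleStep, "resampleStep", 0, strict_lower = TRUE)
  nSeg <- max(7L, round(L0 / resampleStep))
  sNew <- seq(0, L0, length.out = nSeg + 1L)
  x <- stats::approx(sOrig, pts[, 1L], xout = sNew)$y
  y <- stats::approx(sOrig, pts[, 2L], xout = sNew)$y
  dxy <- cbind(diff(x), diff(y))
  thetaRaw <- atan2(dxy[, 2L], dxy[, 1L])
  dth <- diff(thetaRaw)
  dthWrap <- atan2(sin(dth), cos(dth))
  if (any(abs(dthWrap) >= 0.99 * pi))
    stop("tangent angle jump close to pi per step: self-crossing or undersampled filament")
  theta <- thetaRaw[1L] + c(0, cumsum(dthWrap))
  stepLen <- sqrt(rowSums(dxy^2))
  L <- sum(stepLen)                         # resampled (chordal) length
  ds <- L / nSeg
  sMid <- (seq_len(nSeg) - 0.5) * ds
  new("FilamentShape", points = cbind(x, y), s = sMid, theta = theta, L = L)
}

#' Fourier cosine-mode amplitudes of a filament's tangent angles
#'
#' Midpoint discretization of the cosine transform:
#' `a_n = sqrt(2/L) * sum_k theta(s_k) * cos(n*pi*s_k/L) * ds`.
#' The constant (n = 0) term is excluded, making the amplitudes invariant
#' under rigid rotation of the filament.
#'
#' @param shape a [FilamentShape-class] (uniform arclength spacing).
#' @param nMax largest mode number; must not exceed half the number of
#'   tangent samples (aliasing guard).
#' @return numeric vector of amplitudes a_1..a_nMax.
#' @export
fourierModes <- function(shape, nMax = 10L) {
  stopifnot(is(shape, "FilamentShape"))
  assertScalar(nMax, "nMax", 1, integer = TRUE)
  N <- length(shape@theta)
  if (nMax > N / 2)
    stop(sprintf("nMax = %d exceeds half the number of samples (%d): aliasing",
                 as.integer(nMax), N))
  L <- shape@L
  ds <- L / N
  q <- seq_len(nMax) * pi / L
  vapply(seq_len(nMax), function(n) {
    sqrt(2 / L) * sum(shape@theta * cos(n * pi * shape@s / L)) * ds
  }, numeric(1L))
}

#' Ensemble variance of mode amplitudes across filaments
#'
#' Filaments must share their contour length within 5% (mode wavenumbers
#' q_n = n*pi/L are otherwise incomparable across filaments).
#'
#' @param amplitudes matrix (filaments x modes) or list of equal-length
#'   amplitude vectors.
#' @param L numeric vector of filament contour lengths (um), one per
#'   filament, or a single shared length.
#' @param lengthTol relative tolerance on the spread of L (default 0.05).
#' @return a [ModeSpectrum-class] with the unbiased per-mode sample variance.
#' @export
ensembleVariance <- function(amplitudes, L, lengthTol = 0.05) {
  if (is.list(amplitudes)) amplitudes <- do.call(rbind, amplitudes)
  if (!is.matrix(amplitudes)) stop("'amplitudes' must be a matrix or list")
  nf <- nrow(amplitudes)
  if (nf < 2L) stop("ensemble variance needs at least 2 filaments")
  L <- rep_len(as.numeric(L), nf)
  Lm <- mean(L)
  if ((max(L) - min(L)) / Lm > lengthTol)
    stop(sprintf("filament lengths differ by more than %.0f%%: analyze in equal-length batches",
                 100 * lengthTol))
  modes <- seq_len(ncol(amplitudes))
  v <- apply(amplitudes, 2L, stats::var)
  new("ModeSpectrum", modes = as.integer(modes), q = modes * pi / Lm,
      amplitudes = amplitudes, variance = v, L = Lm)
}

#' Fit the inverse-square law to the mode-variance spectrum
#'
#' Least-squares fit of `var = A / q^2` over the chosen modes; the effective
#' persistence length is `Lp* = 1/A`, with a standard error propagated from
#' the fit covariance. A non-positive fitted A yields a failure result
#' (`converged = FALSE`, `lpStar = NA`) with residual diagnostics, never a
#' fake value.
#'
#' @param spectrum a [ModeSpectrum-class].
#' @param modesUsed mode numbers entering the fit (>= 3 modes; default 1-5,
#'   low modes being least affected by localization noise).
#' @return an [LpFit-class].
#' @examples
#' fils <- simulateWLCFilaments(100, contourLength = 5, lpTrue = 10,
#'                              nPoints = 50, seed = 1)
#' sp <- filamentModeSpectrum(fils, nMax = 5)
#' fitPersistenceLength(sp)
#' @export
fitPersistenceLength <- function(spectrum, modesUsed = 1:5) {
  stopifnot(is(spectrum, "ModeSpectrum"))
  modesUsed <- as.integer(modesUsed)
  if (length(modesUsed) < 3L) stop("need at least 3 modes for the fit")
  if (!all(modesUsed %in% spectrum@modes))
    stop("modesUsed outside the computed mode range")
  sel <- match(modesUsed, spectrum@modes)
  v <- spectrum@variance[sel]
  x <- 1 / spectrum@q[sel]^2
  fit <- stats::lm(v ~ 0 + x)
  A <- unname(stats::coef(fit)[1L])
  seA <- suppressWarnings(summary(fit))$coefficients[1L, 2L]  # exact fits warn
  if (!is.finite(A) || A <= 0) {
    return(new("LpFit", lpStar = NA_real_, fitSe = NA_real_,
               modesUsed = modesUsed, residuals = unname(stats::resid(fit)),
               converged = FALSE))
  }
  new("LpFit", lpStar = 1 / A, fitSe = seA / A^2, modesUsed = modesUsed,
      residuals = unname(stats::resid(fit)), converged = TRUE)
}

#' Mode spectrum of a filament set (convenience wrapper)
#'
#' Resamples each filament, computes cosine-mode amplitudes and assembles the
#' ensemble spectrum.
#'
#' @param filaments a [FilamentSet-class] or a data.frame with filament_id,
#'   x_um, y_um.
#' @param nMax largest mode number.
#' @param resampleStep arclength step (um); default per filament.
#' @param lengthTol relative tolerance on contour-length spread across the
#'   batch (see [ensembleVariance()]); localization noise inflates chordal
#'   lengths, so noisy data may need a looser tolerance.
#' @return a [ModeSpectrum-class].
#' @export
filamentModeSpectrum <- function(filaments, nMax = 10L, resampleStep = NULL,
                                 lengthTol = 0.05) {
  if (is.data.frame(filaments)) filaments <- FilamentSet(filaments)
  stopifnot(is(filaments, "FilamentSet"))
  d <- filaments@data
  ids <- unique(d$filament_id)
  amps <- matrix(NA_real_, length(ids), nMax)
  Ls <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sh <- tangentAngles(d[d$filament_id == ids[i], c("x_um", "y_um")],
                        resampleStep = resampleStep)
    amps[i, ] <- fourierModes(sh, nMax)
    Ls[i] <- sh@L
  }
  ensembleVariance(amps, Ls, lengthTol = lengthTol)
}
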