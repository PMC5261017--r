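## Intensity-profile extraction and prominence-based peak counting: the core
## "contact density" statistic. A contact is a local maximum of the (optionally
## baseline-subtracted, smoothed) profile whose topographic prominence reaches
## a stated fraction of the profile's dynamic range, with a minimum physical
## separation between accepted peaks.

#' Peak-detection parameters
#'
#' The detector is deliberately scale-free: the prominence threshold is a
#' fraction of the profile's dynamic range, so multiplying all intensities by
#' a positive constant changes nothing.
#'
#' @param minProminenceFrac required peak prominence as a fraction of the
#'   profile dynamic range, in (0, 1].
#' @param minSeparationUm minimum distance between accepted peaks (um); on
#'   conflict the higher peak is kept.
#' @param baseline "none" or "rolling_median" (running-median subtraction for
#'   uneven background).
#' @param baselineWindowUm window of the rolling median (um); must exceed
#'   `minSeparationUm` when the baseline is active.
#' @param smoothUm sd of the Gaussian pre-smoothing kernel (um); 0 disables
#'   smoothing. Smoothing suppresses single-sample noise maxima whose
#'   prominence would otherwise cross a range-relative threshold at low SNR.
#' @return a list of validated peak parameters.
#' @export
peakParams <- function(minProminenceFrac = 0.2, minSeparationUm = 0.3,
                       baseline = c("none", "rolling_median"),
                       baselineWindowUm = 5, smoothUm = 0.2) {
  baseline <- match.arg(baseline)
  assertScalar(minProminenceFrac, "minProminenceFrac", 0, upper = 1,
               strict_lower = TRUE)
  assertScalar(minSeparationUm, "minSeparationUm", 0)
  assertScalar(smoothUm, "smoothUm", 0)
  if (baseline == "rolling_median") {
    assertScalar(baselineWindowUm, "baselineWindowUm", 0, strict_lower = TRUE)
    if (baselineWindowUm <= minSeparationUm)
      stop("baselineWindowUm must exceed minSeparationUm")
  }
  list(minProminenceFrac = minProminenceFrac,
       minSeparationUm = minSeparationUm,
       baseline = baseline, baselineWindowUm = baselineWindowUm,
       smoothUm = smoothUm)
}

## plateau-aware local maxima (interior for linear profiles) ------------------
localMaximaIdx <- function(y) {
  r <- rle(y)
  k <- length(r$values)
  if (k < 3L) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(k - 1L)
  isMax <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  jj <- j[isMax]
  as.integer(floor((starts[jj] + ends[jj]) / 2))
}

## topographic prominence: descend from the peak on each side until terrain
## rises above the peak (or the profile ends); the peak's base is the higher
## of the two minima found, prominence = height - base.
peakProminence <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(i) {
    h <- y[i]
    j <- i - 1L; lmin <- h
    while (j >= 1L && y[j] <= h) { if (y[j] < lmin) lmin <- y[j]; j <- j - 1L }
    j <- i + 1L; rmin <- h
    while (j <= n && y[j] <= h) { if (y[j] < rmin) rmin <- y[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1L))
}

## Gaussian smoothing in sample units; circular for cyclic profiles, with
## renormalised edge handling otherwise.
gaussSmooth <- function(y, sdSamples, cyclic = FALSE) {
  if (sdSamples <= 0) return(y)
  rad <- max(1L, ceiling(4 * sdSamples))
  k <- stats::dnorm(-rad:rad, sd = sdSamples)
  n <- length(y)
  if (cyclic) {
    left <- y[(((n - rad):(n - 1L)) %% n) + 1L]
    right <- y[((0:(rad - 1L)) %% n) + 1L]
    out <- stats::filter(c(left, y, right), k / sum(k), sides = 2L)
    as.numeric(out[(rad + 1L):(rad + n)])
  } else {
    ypad <- c(rep(y[1L], rad), y, rep(y[n], rad))
    out <- stats::filter(ypad, k / sum(k), sides = 2L)
    as.numeric(out[(rad + 1L):(rad + n)])
  }
}

## running-median baseline
rollingMedianBaseline <- function(y, windowSamples, cyclic = FALSE) {
  k <- max(3L, windowSamples)
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(y)
  if (k >= n) return(rep(stats::median(y), n))
  if (cyclic) {
    rad <- (k - 1L) %/% 2L
    ypad <- c(y[(n - rad + 1L):n], y, y[1L:rad])
    bm <- stats::runmed(ypad, k)
    bm[(rad + 1L):(rad + n)]
  } else {
    stats::runmed(y, k)
  }
}

#' Extract an intensity profile along a straight segment
#'
#' Samples the image by bilinear interpolation at a spacing of at most one
#' pixel along the segment, averaging over `widthPx` parallel lines
#' perpendicular to the path. Positions are converted to micrometres via
#' `pixelSize`.
#'
#' @param image numeric matrix (single-channel image).
#' @param seg a [LineSegment-class] with 0-based (row, col) endpoints.
#' @param pixelSize micrometres per pixel (> 0).
#' @param sourceId identifier stored on the profile.
#' @return an [IntensityProfile-class].
#' @examples
#' img <- matrix(rep(0:9, each = 5), 5, 10, byrow = FALSE)
#' p <- extractProfile(t(img), LineSegment(c(2, 0), c(2, 9)), pixelSize = 1)
#' @export
extractProfile <- function(image, seg, pixelSize, sourceId = "") {
  assertMatrixImage(image)
  stopifnot(is(seg, "LineSegment"))
  assertScalar(pixelSize, "pixelSize", 0, strict_lower = TRUE)
  nr <- nrow(image); nc <- ncol(image)
  p0 <- seg@p0; p1 <- seg@p1
  d <- p1 - p0
  lenPx <- sqrt(sum(d^2))
  u <- d / lenPx                      # unit direction (row, col)
  nrm <- c(-u[2L], u[1L])             # unit normal
  w <- max(1L, round(seg@widthPx))
  offs <- if (w == 1L) 0 else seq(-(w - 1) / 2, (w - 1) / 2, length.out = w)
  # bounds check including the averaging band
  extR <- range(c(p0[1L], p1[1L])) + range(offs * nrm[1L])
  extC <- range(c(p0[2L], p1[2L])) + range(offs * nrm[2L])
  if (extR[1L] < 0 || extR[2L] > nr - 1L || extC[1L] < 0 || extC[2L] > nc - 1L)
    stop("segment (including averaging width) is out of image bounds")
  nSamp <- max(2L, as.integer(ceiling(lenPx)) + 1L)
  tt <- seq(0, 1, length.out = nSamp)
  rowP <- p0[1L] + tt * d[1L]
  colP <- p0[2L] + tt * d[2L]
  acc <- numeric(nSamp)
  for (o in offs) {
    acc <- acc + bilinearAt(image, rowP + o * nrm[1L], colP + o * nrm[2L])
  }
  IntensityProfile(s = tt * lenPx * pixelSize, intensity = acc / length(offs),
                   sourceId = sourceId)
}

#' Count intensity peaks ("contacts") along a profile
#'
#' A contact is a local maximum whose topographic prominence is at least
#' `minProminenceFrac` times the profile's dynamic range, computed after the
#' optional rolling-median baseline subtraction and Gaussian smoothing.
#' Accepted peaks are at least `minSeparationUm` apart; when two candidates
#' conflict, the higher one is kept. Cyclic profiles (cell perimeters) are
#' treated as periodic: the profile is rotated so the cut sits at the global
#' minimum, where the linear and circular prominences coincide.
#'
#' A flat profile (zero dynamic range) has zero contacts and is not an error.
#'
#' @param profile an [IntensityProfile-class].
#' @param params a [peakParams()] list.
#' @return a list with `n` (count) and `positions` (peak positions, um,
#'   sorted increasing).
#' @examples
#' s <- seq(0, 10, by = 0.05)
#' y <- exp(-(s - 3)^2 / 0.08) + exp(-(s - 7)^2 / 0.08)
#' countContacts(IntensityProfile(s, y))$n
#' @export
countContacts <- function(profile, params = peakParams()) {
  stopifnot(is(profile, "IntensityProfile"))
  s <- profile@s
  y <- profile@intensity
  n <- length(y)
  ds <- mean(diff(s))
  cyclic <- profile@cyclic

  if (params$baseline == "rolling_median") {
    wS <- max(3L, round(params$baselineWindowUm / ds))
    y <- y - rollingMedianBaseline(y, wS, cyclic = cyclic)
  }
  if (params$smoothUm > 0) {
    y <- gaussSmooth(y, params$smoothUm / ds, cyclic = cyclic)
  }
  rng <- max(y) - min(y)
  if (rng <= 0) return(list(n = 0L, positions = numeric()))

  if (cyclic) {
    rot <- which.min(y)
    ord <- c(rot:n, seq_len(rot - 1L))
    yr <- y[ord]
    peaksRot <- localMaximaIdx(yr)
    prom <- peakProminence(yr, peaksRot)
    keep <- prom >= params$minProminenceFrac * rng
    peakIdx <- ord[peaksRot[keep]]
    heights <- yr[peaksRot[keep]]
    totalLen <- max(s) + ds                 # closing the contour
    dist2 <- function(i, j) {
      dd <- abs(s[i] - s[j]); pmin(dd, totalLen - dd)
    }
  } else {
    peakIdx <- localMaximaIdx(y)
    prom <- peakProminence(y, peakIdx)
    keep <- prom >= params$minProminenceFrac * rng
    peakIdx <- peakIdx[keep]
    heights <- y[peakIdx]
    dist2 <- function(i, j) abs(s[i] - s[j])
  }

  if (length(peakIdx) && params$minSeparationUm > 0) {
    ordH <- order(heights, decreasing = TRUE)
    accepted <- integer()
    for (i in peakIdx[ordH]) {
      if (!length(accepted) ||
          all(dist2(i, accepted) >= params$minSeparationUm)) {
        accepted <- c(accepted, i)
      }
    }
    peakIdx <- sort(accepted)
  } else {
    peakIdx <- sort(peakIdx)
  }
  list(n = length(peakIdx), positions = s[peakIdx])
}

#' Build a ContactRegion by counting contacts on a profile
#'
#' @param profile an [IntensityProfile-class] along a constant-gap segment.
#' @param cellGapUm the segment's constant cell-cell distance (um).
#' @param regionId identifier.
#' @param params [peakParams()].
#' @return a [ContactRegion-class] with its contact count and density
#'   (contacts per micrometre of profile).
#' @export
contactRegion <- function(profile, cellGapUm, regionId = "region",
                          params = peakParams()) {
  cc <- countContacts(profile, params)
  L <- profileLength(profile)
  new("ContactRegion", regionId = as.character(regionId), profile = profile,
      cellGapUm = as.numeric(cellGapUm), nContacts = as.integer(cc$n),
      peakPositions = cc$positions, density = cc$n / L)
}

#' Contact density of a region
#'
#' The defining statistic: the number of contacts divided by the physical
#' length of the sampled profile.
#'
#' @param region a [ContactRegion-class].
#' @return contacts per micrometre.
#' @export
contactDensity <- function(region) {
  stopifnot(is(region, "ContactRegion"))
  L <- profileLength(region@profile)
  if (L <= 0) stop("zero-length profile")
  region@nContacts / L
}

#' Split a gap trace into maximal constant-distance segments
#'
#' Scanning left to right, each segment is extended as far as possible while
#' the gap's running range (max - min) stays within `tolGap`; the next
#' segment starts at the first sample that breaks the tolerance. Segments are
#' therefore disjoint, ordered and maximal under the left-to-right greedy
#' rule.
#'
#' @param gapTrace data.frame (or list) with numeric `s` (um, increasing) and
#'   `gap` (um).
#' @param tolGap tolerance on the within-segment gap range (um).
#' @return data.frame with columns start_idx, end_idx (1-based sample
#'   indices), s_start, s_end, cell_gap_um (mean gap), n_samples.
#' @examples
#' tr <- data.frame(s = 0:9, gap = c(rep(2, 5), rep(8, 5)))
#' segmentConstantGap(tr, tolGap = 1)
#' @export
segmentConstantGap <- function(gapTrace, tolGap) {
  s <- gapTrace$s; g <- gapTrace$gap
  if (length(s) < 2L) stop("gap trace needs at least 2 samples")
  if (any(diff(s) <= 0)) stop("s must be strictly increasing")
  assertScalar(tolGap, "tolGap", 0)
  n <- length(g)
  out <- NULL
  i <- 1L
  while (i <= n) {
    lo <- g[i]; hi <- g[i]; j <- i
    while (j < n) {
      lo2 <- min(lo, g[j + 1L]); hi2 <- max(hi, g[j + 1L])
      if (hi2 - lo2 > tolGap) break
      lo <- lo2; hi <- hi2; j <- j + 1L
    }
    out <- rbind(out, data.frame(start_idx = i, end_idx = j,
                                 s_start = s[i], s_end = s[j],
                                 cell_gap_um = mean(g[i:j]),
                                 n_samples = j - i + 1L))
    i <- j + 1L
  }
  rownames(out) <- NULL
  out
}
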