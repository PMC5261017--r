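## Ground-truthed synthetic inputs for every analysis stage. Each generator is
## a pure function of its parameters including the seed: identical calls give
## bit-identical output, and the caller's RNG state is left untouched.

## contact placement with a guaranteed minimum separation ---------------------
## Uniformly places k positions in [buffer, L - buffer] with pairwise spacing
## >= minSep, by the order-statistics ("stick") construction: draw k sorted
## uniforms on the slack interval and add back the mandatory gaps.
placeSeparated <- function(k, L, minSep, buffer) {
  if (k == 0L) return(numeric())
  slack <- (L - 2 * buffer) - (k - 1L) * minSep
  if (slack < 0) {
    stop(sprintf(
      "cannot place %d contacts with minimum separation %g um in %g um: peaks closer than 2x width would overlap",
      k, minSep, L), call. = FALSE)
  }
  u <- sort(stats::runif(k, 0, slack))
  buffer + u + (seq_len(k) - 1L) * minSep
}

## anisotropic Gaussian bump added in place
addBump <- function(image, row0, col0, sigmaRowPx, sigmaColPx, amplitude) {
  nr <- nrow(image); nc <- ncol(image)
  rr <- max(0L, floor(row0 - 4 * sigmaRowPx)):min(nr - 1L, ceiling(row0 + 4 * sigmaRowPx))
  cc <- max(0L, floor(col0 - 4 * sigmaColPx)):min(nc - 1L, ceiling(col0 + 4 * sigmaColPx))
  bump <- amplitude *
    exp(-(outer((rr - row0)^2 / (2 * sigmaRowPx^2),
                (cc - col0)^2 / (2 * sigmaColPx^2), "+")))
  image[rr + 1L, cc + 1L] <- image[rr + 1L, cc + 1L] + bump
  image
}

#' Simulate a two-cell contact scene with known contact positions
#'
#' Renders one or more horizontal cell-cell regions: two rectangular cell
#' bodies separated by a constant gap, with filopodial "contacts" drawn as
#' Gaussian intensity bumps (sd `peakWidthUm` along the gap, elongated across
#' it) centred on the inter-cell midline, and optional filopodia bumps along
#' each cell's outer boundary. Additive Gaussian read noise of sd `noiseSd`
#' is applied last, so `peakAmplitude / noiseSd` is the scene SNR. Peak
#' widths are full widths at half maximum (FWHM); the underlying Gaussian sd
#' is FWHM / 2.355. Contact bumps are elongated across the gap (sd = half the
#' gap), as a filopodium bridging the two cells would be.
#'
#' Ground-truth contact positions are separated by at least `2 * peakWidthUm`;
#' a request that cannot satisfy this is rejected.
#'
#' @param imageShape integer (rows, cols) in pixels.
#' @param pixelSize micrometres per pixel (> 0).
#' @param contactsPerRegion integer vector, contacts for each region; its
#'   length sets the number of regions.
#' @param regionLengthUm length of each constant-gap segment (um).
#' @param cellGapUm cell-cell distance per region (um), recycled.
#' @param peakWidthUm FWHM of a contact bump along the profile (um).
#' @param peakAmplitude bump amplitude (a.u.).
#' @param background background intensity (a.u.).
#' @param noiseSd sd of additive Gaussian read noise (a.u.).
#' @param filopodiaPerCell number of filopodia bumps on each cell's outer
#'   boundary.
#' @param cellBodyFrac cell-body intensity as a fraction of `peakAmplitude`.
#' @param seed integer seed; the scene is a pure function of its arguments.
#' @return a list with elements `image` (numeric matrix), `truth` (list with
#'   `regions`, `contacts`, `filopodia` data.frames and `cellMasks`, a list of
#'   logical matrices), `pixelSize`, and `params` (argument echo).
#' @examples
#' sc <- simulateContactScene(contactsPerRegion = 5, noiseSd = 0, seed = 1)
#' nrow(sc$truth$contacts)
#' @export
simulateContactScene <- function(imageShape = c(160L, 360L),
                                 pixelSize = 0.1,
                                 contactsPerRegion = c(5L),
                                 regionLengthUm = 24,
                                 cellGapUm = 2,
                                 peakWidthUm = 0.7,
                                 peakAmplitude = 1,
                                 background = 0.1,
                                 noiseSd = 0,
                                 filopodiaPerCell = 0L,
                                 cellBodyFrac = 0.25,
                                 seed = 1L) {
  assertScalar(pixelSize, "pixelSize", 0, strict_lower = TRUE)
  assertScalar(regionLengthUm, "regionLengthUm", 0, strict_lower = TRUE)
  assertScalar(peakWidthUm, "peakWidthUm", 0, strict_lower = TRUE)
  assertScalar(peakAmplitude, "peakAmplitude", 0, strict_lower = TRUE)
  assertScalar(background, "background", 0)
  assertScalar(noiseSd, "noiseSd", 0)
  assertScalar(filopodiaPerCell, "filopodiaPerCell", 0, integer = TRUE)
  if (any(contactsPerRegion < 0))
    stop("contactsPerRegion must be non-negative counts")
  nRegions <- length(contactsPerRegion)
  cellGapUm <- rep_len(cellGapUm, nRegions)
  if (any(cellGapUm < 0)) stop("cellGapUm must be >= 0")
  rows <- as.integer(imageShape[1L]); cols <- as.integer(imageShape[2L])
  snr <- peakAmplitude / max(noiseSd, .Machine$double.eps)
  if (!is.finite(snr)) stop("SNR must be finite")

  lenPx <- regionLengthUm / pixelSize
  if (lenPx > cols - 4L)
    stop("regionLengthUm does not fit inside the image width")
  bandH <- rows / nRegions
  maxGapPx <- max(cellGapUm) / pixelSize
  if (bandH < maxGapPx + 12)
    stop("image rows too small for the requested regions and gaps")

  withSeed(seed, {
    img <- matrix(background, rows, cols)
    x0 <- floor((cols - lenPx) / 2)          # 0-based col of profile start
    regions <- data.frame(region_id = sprintf("region%02d", seq_len(nRegions)),
                          row_px = NA_real_, x0_px = x0,
                          x1_px = x0 + lenPx,
                          gap_um = cellGapUm,
                          length_um = regionLengthUm)
    contacts <- NULL; filopodia <- NULL; cellMasks <- list()
    sigPx <- peakWidthUm / 2.355 / pixelSize   # FWHM -> Gaussian sd, in px

    for (i in seq_len(nRegions)) {
      bandTop <- round((i - 1L) * bandH)          # 0-based row bounds
      bandBot <- round(i * bandH) - 1L
      mid <- (bandTop + bandBot) / 2
      regions$row_px[i] <- mid
      gapPx <- cellGapUm[i] / pixelSize
      topLo <- bandTop + 3L; topHi <- floor(mid - gapPx / 2)
      botLo <- ceiling(mid + gapPx / 2); botHi <- bandBot - 3L
      c0 <- x0; c1 <- x0 + lenPx

      for (side in c("top", "bottom")) {
        maskRows <- if (side == "top") topLo:topHi else botLo:botHi
        mask <- matrix(FALSE, rows, cols)
        mask[maskRows + 1L, (c0:c1) + 1L] <- TRUE
        img[mask] <- img[mask] + cellBodyFrac * peakAmplitude
        cellId <- sprintf("cell_%02d_%s", i, side)

        fil_s <- placeSeparated(filopodiaPerCell, regionLengthUm,
                                2 * peakWidthUm, 2 * peakWidthUm)
        outerRow <- if (side == "top") topLo else botHi
        for (sf in fil_s) {
          img <- addBump(img, outerRow, c0 + sf / pixelSize, sigPx, sigPx,
                         peakAmplitude)
        }
        if (filopodiaPerCell > 0L) {
          filopodia <- rbind(filopodia, data.frame(
            cell_id = cellId, s_um = fil_s,
            row_px = outerRow, col_px = c0 + fil_s / pixelSize))
        }
        cellMasks[[cellId]] <- mask
      }

      s_i <- placeSeparated(contactsPerRegion[i], regionLengthUm,
                            2 * peakWidthUm, 2 * peakWidthUm)
      sigRow <- max(gapPx / 2, sigPx)
      for (s in s_i) {
        img <- addBump(img, mid, x0 + s / pixelSize, sigRow, sigPx,
                       peakAmplitude)
      }
      if (length(s_i)) {
        contacts <- rbind(contacts, data.frame(
          region_id = regions$region_id[i], s_um = s_i,
          row_px = mid, col_px = x0 + s_i / pixelSize))
      }
    }

    if (noiseSd > 0) img <- img + matrix(stats::rnorm(rows * cols, 0, noiseSd),
                                         rows, cols)
    list(image = img,
         truth = list(
           regions = regions,
           contacts = if (is.null(contacts))
             data.frame(region_id = character(), s_um = numeric(),
                        row_px = numeric(), col_px = numeric()) else contacts,
           filopodia = if (is.null(filopodia))
             data.frame(cell_id = character(), s_um = numeric(),
                        row_px = numeric(), col_px = numeric()) else filopodia,
           cellMasks = cellMasks),
         pixelSize = pixelSize,
         params = list(imageShape = c(rows, cols), pixelSize = pixelSize,
                       contactsPerRegion = contactsPerRegion,
                       regionLengthUm = regionLengthUm, cellGapUm = cellGapUm,
                       peakWidthUm = peakWidthUm, peakAmplitude = peakAmplitude,
                       background = background, noiseSd = noiseSd,
                       filopodiaPerCell = filopodiaPerCell,
                       cellBodyFrac = cellBodyFrac, seed = seed))
  })
}

#' Profile segments along the inter-cell midlines of a synthetic scene
#'
#' @param scene result of [simulateContactScene()].
#' @param widthPx perpendicular averaging width for profile extraction.
#' @return a list of [LineSegment-class] objects, one per region.
#' @export
sceneSegments <- function(scene, widthPx = 15) {
  reg <- scene$truth$regions
  lapply(seq_len(nrow(reg)), function(i) {
    LineSegment(p0 = c(reg$row_px[i], reg$x0_px[i]),
                p1 = c(reg$row_px[i], reg$x1_px[i]),
                widthPx = widthPx)
  })
}

#' Simulate 2-D cell trajectories (Brownian or persistent random walk)
#'
#' Displacement steps have stationary per-component variance `2 * D * dt`.
#' With `persistenceTime > 0` successive steps are AR(1)-correlated with
#' coefficient `exp(-dt / persistenceTime)`, so the short-lag MSD of a
#' persistent walker exceeds the `4 * D * t` line of an uncorrelated walk with
#' the same single-step variance; `persistenceTime = 0` gives a pure Brownian
#' walk.
#'
#' @param nTraj number of trajectories (>= 1).
#' @param nSteps number of steps per trajectory (>= 1); each trajectory has
#'   `nSteps + 1` points at uniform spacing `dt`.
#' @param dt frame interval (min, > 0).
#' @param D diffusion coefficient (um^2/min, >= 0).
#' @param persistenceTime directional persistence time (min, >= 0).
#' @param seed integer seed.
#' @return a [TrajectorySet-class]; all trajectories start at the origin.
#' @examples
#' trajs <- simulateTrajectories(nTraj = 10, nSteps = 20, dt = 20, D = 1,
#'                               seed = 1)
#' @export
simulateTrajectories <- function(nTraj, nSteps, dt, D, persistenceTime = 0,
                                 seed = 1L) {
  assertScalar(nTraj, "nTraj", 1, integer = TRUE)
  assertScalar(nSteps, "nSteps", 1, integer = TRUE)
  assertScalar(dt, "dt", 0, strict_lower = TRUE)
  assertScalar(D, "D", 0)
  assertScalar(persistenceTime, "persistenceTime", 0)
  withSeed(seed, {
    stepSd <- sqrt(2 * D * dt)
    rho <- if (persistenceTime > 0) exp(-dt / persistenceTime) else 0
    mkSteps <- function() {
      xi <- matrix(stats::rnorm(nSteps * nTraj, 0, stepSd), nSteps, nTraj)
      if (rho > 0 && nSteps > 1L) {
        v <- xi
        for (k in 2:nSteps) v[k, ] <- rho * v[k - 1L, ] + sqrt(1 - rho^2) * xi[k, ]
        v
      } else xi
    }
    dx <- mkSteps(); dy <- mkSteps()
    x <- rbind(0, apply(dx, 2L, cumsum))
    y <- rbind(0, apply(dy, 2L, cumsum))
    if (nSteps == 1L) { x <- rbind(0, dx); y <- rbind(0, dy) }
    t <- (0:nSteps) * dt
    TrajectorySet(data.frame(
      cell_id = rep(sprintf("cell%04d", seq_len(nTraj)), each = nSteps + 1L),
      t_min = rep(t, times = nTraj),
      x_um = as.vector(x), y_um = as.vector(y)), dt = dt)
  })
}

#' Simulate a 2-D worm-like-chain filament ensemble
#'
#' Tangent-angle increments over an arclength step `ds` are drawn i.i.d.
#' Gaussian with variance `ds / lpTrue` (the 2-D worm-like-chain convention),
#' giving `Var[theta(s) - theta(0)] = s / lpTrue`. Points are spaced uniformly
#' in arclength; optional localization noise is added to the coordinates
#' afterwards.
#'
#' @param nFilaments number of filaments (>= 1).
#' @param contourLength filament contour length (um, > 0).
#' @param lpTrue ground-truth persistence length (um, > 0).
#' @param nPoints number of digitised points per filament (>= 8).
#' @param localizationNoiseSd sd of isotropic Gaussian coordinate noise (um).
#' @param seed integer seed.
#' @return a [FilamentSet-class].
#' @examples
#' fils <- simulateWLCFilaments(nFilaments = 5, contourLength = 5,
#'                              lpTrue = 10, nPoints = 50, seed = 1)
#' @export
simulateWLCFilaments <- function(nFilaments, contourLength, lpTrue,
                                 nPoints = 50L, localizationNoiseSd = 0,
                                 seed = 1L) {
  assertScalar(nFilaments, "nFilaments", 1, integer = TRUE)
  assertScalar(contourLength, "contourLength", 0, strict_lower = TRUE)
  assertScalar(lpTrue, "lpTrue", 0, strict_lower = TRUE)
  assertScalar(nPoints, "nPoints", 8, integer = TRUE)
  assertScalar(localizationNoiseSd, "localizationNoiseSd", 0)
  withSeed(seed, {
    ds <- contourLength / (nPoints - 1L)
    out <- vector("list", nFilaments)
    for (f in seq_len(nFilaments)) {
      theta0 <- stats::runif(1L, 0, 2 * pi)
      dtheta <- stats::rnorm(nPoints - 2L, 0, sqrt(ds / lpTrue))
      theta <- theta0 + c(0, cumsum(dtheta))   # angle of each of nPoints-1 segments
      x <- c(0, cumsum(ds * cos(theta)))
      y <- c(0, cumsum(ds * sin(theta)))
      if (localizationNoiseSd > 0) {
        x <- x + stats::rnorm(nPoints, 0, localizationNoiseSd)
        y <- y + stats::rnorm(nPoints, 0, localizationNoiseSd)
      }
      out[[f]] <- data.frame(filament_id = sprintf("fil%04d", f),
                             x_um = x, y_um = y)
    }
    FilamentSet(do.call(rbind, out))
  })
}

#' Simulate a homogeneous Poisson point pattern of cells and its rendering
#'
#' Cell centres follow a homogeneous Poisson process of the given intensity
#' over the field; each cell is a disk whose radius has mean
#' `meanCellRadius` and coefficient of variation `radiusCv` (gamma
#' distributed; `radiusCv = 0` gives equal radii). The binary mask is
#' rasterised at `pixelSize`; disks are clipped at the field boundary.
#'
#' @param fieldSize numeric (width, height) of the field (um).
#' @param intensity expected cells per square micrometre (> 0).
#' @param meanCellRadius mean disk radius (um, > 0).
#' @param radiusCv coefficient of variation of the radius (>= 0).
#' @param pixelSize rasterisation step (um/px).
#' @param seed integer seed.
#' @return a list: `mask` (logical matrix), `truth` (data.frame x_um, y_um,
#'   r_um), `pixelSize`, `fieldSize`, `overlapWarning` (character or NULL;
#'   recorded when the probability that a disk touches another exceeds 0.5),
#'   and `params`.
#' @examples
#' pp <- simulatePointPattern(fieldSize = c(100, 100), intensity = 2e-4,
#'                            meanCellRadius = 2, seed = 1)
#' @export
simulatePointPattern <- function(fieldSize, intensity, meanCellRadius,
                                 radiusCv = 0, pixelSize = 1, seed = 1L) {
  stopifnot(length(fieldSize) == 2L, all(fieldSize > 0))
  assertScalar(intensity, "intensity", 0, strict_lower = TRUE)
  assertScalar(meanCellRadius, "meanCellRadius", 0, strict_lower = TRUE)
  assertScalar(radiusCv, "radiusCv", 0)
  assertScalar(pixelSize, "pixelSize", 0, strict_lower = TRUE)
  W <- fieldSize[1L]; H <- fieldSize[2L]
  withSeed(seed, {
    n <- stats::rpois(1L, intensity * W * H)
    x <- stats::runif(n, 0, W); y <- stats::runif(n, 0, H)
    r <- if (radiusCv == 0) rep(meanCellRadius, n)
         else stats::rgamma(n, shape = 1 / radiusCv^2,
                            scale = meanCellRadius * radiusCv^2)
    nc <- ceiling(W / pixelSize); nr <- ceiling(H / pixelSize)
    mask <- matrix(FALSE, nr, nc)
    for (i in seq_len(n)) {
      cLo <- max(1L, floor((x[i] - r[i]) / pixelSize) + 1L)
      cHi <- min(nc, ceiling((x[i] + r[i]) / pixelSize))
      rLo <- max(1L, floor((y[i] - r[i]) / pixelSize) + 1L)
      rHi <- min(nr, ceiling((y[i] + r[i]) / pixelSize))
      if (cLo > cHi || rLo > rHi) next
      px <- (cLo:cHi - 0.5) * pixelSize
      py <- (rLo:rHi - 0.5) * pixelSize
      hit <- outer((py - y[i])^2, (px - x[i])^2, "+") <= r[i]^2
      mask[rLo:rHi, cLo:cHi] <- mask[rLo:rHi, cLo:cHi] | hit
    }
    pTouch <- 1 - exp(-intensity * pi * (2 * meanCellRadius)^2)
    warn <- if (pTouch > 0.5)
      sprintf("disk overlap probability %.2f exceeds 0.5; rendered components may merge", pTouch)
    list(mask = mask,
         truth = data.frame(x_um = x, y_um = y, r_um = r),
         pixelSize = pixelSize, fieldSize = c(W, H),
         overlapWarning = warn,
         params = list(fieldSize = c(W, H), intensity = intensity,
                       meanCellRadius = meanCellRadius, radiusCv = radiusCv,
                       pixelSize = pixelSize, seed = seed))
  })
}

#' Simulate differential-expression tables with planted regulated sets
#'
#' Regulated genes receive a signed linear fold change with magnitude drawn
#' uniformly from `fcMagnitudeRange` and a p-value below `pRegulatedMax`;
#' unregulated genes receive |fold change| in (1, 2) (signed linear
#' convention: values in (-1, 1) do not occur) and a uniform p-value. With
#' `twoComparisons = TRUE` a second table with the same planted membership but
#' freshly drawn magnitudes and p-values is returned, emulating two
#' independent comparisons sharing their regulated programme.
#'
#' @param nGenes number of genes.
#' @param fracUp,fracDown fractions of up-/downregulated genes (sum <= 1).
#' @param fcMagnitudeRange (min, max) linear fold-change magnitude, > 1.
#' @param pRegulatedMax maximum p-value assigned to regulated genes.
#' @param twoComparisons return two tables with shared truth sets.
#' @param seed integer seed.
#' @return a list: `tables` (list of one or two data.frames with columns
#'   gene, fold_change, p_value), `truth` (list with `up` and `down` gene
#'   sets), `params`.
#' @examples
#' de <- simulateDETables(nGenes = 100, fracUp = 0.1, fracDown = 0.1, seed = 1)
#' @export
simulateDETables <- function(nGenes, fracUp, fracDown,
                             fcMagnitudeRange = c(3, 5),
                             pRegulatedMax = 0.01,
                             twoComparisons = FALSE, seed = 1L) {
  assertScalar(nGenes, "nGenes", 1, integer = TRUE)
  assertScalar(fracUp, "fracUp", 0, upper = 1)
  assertScalar(fracDown, "fracDown", 0, upper = 1)
  if (fracUp + fracDown > 1) stop("fracUp + fracDown must be <= 1")
  stopifnot(length(fcMagnitudeRange) == 2L, all(fcMagnitudeRange > 1),
            diff(fcMagnitudeRange) >= 0)
  assertScalar(pRegulatedMax, "pRegulatedMax", 0, upper = 1,
               strict_lower = TRUE)
  withSeed(seed, {
    genes <- sprintf("g%05d", seq_len(nGenes))
    nUp <- round(fracUp * nGenes); nDown <- round(fracDown * nGenes)
    perm <- sample(genes)
    up <- sort(perm[seq_len(nUp)])
    down <- sort(perm[nUp + seq_len(nDown)])
    drawTable <- function() {
      fc <- numeric(nGenes); p <- numeric(nGenes)
      names(fc) <- names(p) <- genes
      fc[up] <- stats::runif(nUp, fcMagnitudeRange[1L], fcMagnitudeRange[2L])
      fc[down] <- -stats::runif(nDown, fcMagnitudeRange[1L], fcMagnitudeRange[2L])
      p[c(up, down)] <- stats::runif(nUp + nDown, 0, pRegulatedMax)
      rest <- setdiff(genes, c(up, down))
      fc[rest] <- sample(c(-1, 1), length(rest), replace = TRUE) *
        stats::runif(length(rest), 1 + 1e-6, 2 - 1e-6)
      p[rest] <- stats::runif(length(rest))
      data.frame(gene = genes, fold_change = unname(fc),
                 p_value = unname(p))
    }
    tables <- list(drawTable())
    if (twoComparisons) tables <- c(tables, list(drawTable()))
    list(tables = tables, truth = list(up = up, down = down),
         params = list(nGenes = nGenes, fracUp = fracUp, fracDown = fracDown,
                       fcMagnitudeRange = fcMagnitudeRange,
                       pRegulatedMax = pRegulatedMax,
                       twoComparisons = twoComparisons, seed = seed))
  })
}
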