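## Distance-to-first-neighbor analysis: binarize, label connected components,
## centroid distances normalized to the mean equivalent cell radius, KDE
## curves and the two-sample KS comparison.

#' Binarize a single-channel image
#'
#' With `method = "otsu"` the threshold is computed by Otsu's method on the
#' image rescaled to [0, 1] (via EBImage) and mapped back to intensity units;
#' a constant image has no separable classes and is rejected. With
#' `method = "fixed"` the supplied threshold is used. Foreground is strictly
#' above the threshold (`image > t`).
#'
#' @param image numeric matrix.
#' @param method "otsu" or "fixed".
#' @param threshold threshold in intensity units (required for "fixed").
#' @return logical mask with attributes `method` and `threshold`.
#' @export
binarizeImage <- function(image, method = c("otsu", "fixed"),
                          threshold = NULL) {
  assertMatrixImage(image)
  method <- match.arg(method)
  rng <- range(image)
  if (method == "otsu") {
    if (diff(rng) == 0)
      stop("constant image: Otsu thresholding has no separable classes")
    norm <- (image - rng[1L]) / diff(rng)
    tNorm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    threshold <- rng[1L] + tNorm * diff(rng)
  } else {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold")
    assertScalar(threshold, "threshold")
  }
  mask <- image > threshold
  attr(mask, "method") <- method
  attr(mask, "threshold") <- threshold
  mask
}

## neighbor shifts for the two connectivities (row, col offsets)
connShifts <- function(connectivity) {
  s4 <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 4L) s4
  else rbind(s4, c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
}

## Connected-component labeling by iterative minimum-label propagation:
## every foreground pixel starts with its own id (its linear index) and
## repeatedly adopts the minimum id among its foreground neighbors until a
## fixed point. Labels are then renumbered 1..K in order of each component's
## smallest linear index (deterministic).
labelMatrix <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nr, nc))
  lab[idx] <- idx
  shifts <- connShifts(connectivity)
  repeat {
    nxt <- lab
    for (k in seq_len(nrow(shifts))) {
      dr <- shifts[k, 1L]; dc <- shifts[k, 2L]
      rs <- max(1L, 1L + dr):min(nr, nr + dr)  # destination rows
      cs <- max(1L, 1L + dc):min(nc, nc + dc)
      nb <- matrix(Inf, nr, nc)
      nb[rs, cs] <- lab[rs - dr, cs - dc]
      nxt <- pmin(nxt, nb)
    }
    nxt[!mask] <- Inf
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  vals <- sort(unique(lab[idx]))
  out <- matrix(0L, nr, nc)
  out[idx] <- match(lab[idx], vals)
  out
}

#' Label connected components of a binary mask
#'
#' Deterministic labeling (components numbered in raster order of their first
#' pixel) with selectable 4- or 8-connectivity, plus a per-object table of
#' centroids, areas and equivalent-circle radii. With 8-connectivity,
#' diagonally touching cells merge into one object ("cell cluster").
#'
#' Coordinates: pixel (r, c) (0-based) has physical position
#' `x = c * pixelSize`, `y = r * pixelSize`.
#'
#' @param mask logical matrix (output of [binarizeImage()] or a synthetic
#'   ground-truth mask). An empty mask yields an empty object table.
#' @param connectivity 4 or 8 (default 8).
#' @param pixelSize micrometres per pixel.
#' @return a [LabeledField-class].
#' @export
labelComponents <- function(mask, connectivity = 8L, pixelSize = 1) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!is.matrix(mask)) stop("'mask' must be a matrix")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  assertScalar(pixelSize, "pixelSize", 0, strict_lower = TRUE)
  lab <- labelMatrix(mask, connectivity)
  k <- max(lab)
  if (k == 0L) {
    obj <- data.frame(label = integer(), row = numeric(), col = numeric(),
                      area_px = integer(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(),
                      equivalent_radius_um = numeric())
  } else {
    idx <- which(lab > 0L)
    lv <- lab[idx]
    rows0 <- (idx - 1L) %% nrow(mask)       # 0-based row
    cols0 <- (idx - 1L) %/% nrow(mask)      # 0-based col
    area <- tabulate(lv, nbins = k)
    crow <- as.numeric(rowsum(rows0, lv)) / area
    ccol <- as.numeric(rowsum(cols0, lv)) / area
    obj <- data.frame(label = seq_len(k), row = crow, col = ccol,
                      area_px = area,
                      centroid_x_um = ccol * pixelSize,
                      centroid_y_um = crow * pixelSize,
                      equivalent_radius_um =
                        sqrt(area * pixelSize^2 / pi))
  }
  meta <- list(method = attr(mask, "method"),
               threshold = attr(mask, "threshold"))
  new("LabeledField", mask = matrix(as.logical(mask), nrow(mask), ncol(mask)),
      labels = lab, objects = obj, pixelSize = pixelSize,
      connectivity = connectivity, meta = meta)
}

#' Nearest-neighbor distances of a point set
#'
#' @param xy two-column matrix or data.frame of (x, y) positions (um).
#' @param edge edge handling: "none" (plain Euclidean; slight upward bias for
#'   points near the field border) or "torus" (periodic boundary; unbiased
#'   for homogeneous patterns, requires `fieldSize`).
#' @param fieldSize numeric (width, height) of the field (um), for "torus".
#' @return numeric vector of first-neighbor distances, one per point.
#' @export
nnDistances <- function(xy, edge = c("none", "torus"), fieldSize = NULL) {
  edge <- match.arg(edge)
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 points")
  dx <- abs(outer(xy[, 1L], xy[, 1L], "-"))
  dy <- abs(outer(xy[, 2L], xy[, 2L], "-"))
  if (edge == "torus") {
    if (is.null(fieldSize) || length(fieldSize) != 2L)
      stop("edge = 'torus' requires fieldSize = c(width, height)")
    dx <- pmin(dx, fieldSize[1L] - dx)
    dy <- pmin(dy, fieldSize[2L] - dy)
  }
  d2 <- dx^2 + dy^2
  diag(d2) <- Inf
  sqrt(apply(d2, 1L, min))
}

#' First-neighbor distances of labeled cells/clusters
#'
#' For every labeled object, the centroid distance to its nearest other
#' object. Normalized distances divide by the mean equivalent-circle radius
#' over the field ("average cell radius").
#'
#' @param field a [LabeledField-class] with >= 2 objects.
#' @param allPairs also return the full centroid distance matrix.
#' @param edge,fieldSize see [nnDistances()].
#' @return a [NeighborDistances-class].
#' @export
firstNeighborDistances <- function(field, allPairs = FALSE,
                                   edge = c("none", "torus"),
                                   fieldSize = NULL) {
  stopifnot(is(field, "LabeledField"))
  obj <- field@objects
  if (nrow(obj) < 2L) stop("need at least 2 labeled objects")
  xy <- cbind(obj$centroid_x_um, obj$centroid_y_um)
  d <- nnDistances(xy, edge = edge, fieldSize = fieldSize)
  meanR <- mean(obj$equivalent_radius_um)
  ap <- if (allPairs) {
    m <- as.matrix(stats::dist(xy)); dimnames(m) <- NULL; m
  } else matrix(numeric(), 0L, 0L)
  new("NeighborDistances", distances = d, normalized = d / meanR,
      meanRadius = meanR, allPairs = ap)
}

#' Compare two distance distributions (two-sample KS + KDE curves)
#'
#' The KS statistic is the exact sup-difference of the two empirical CDFs.
#' The p-value uses the exact null distribution when the sample sizes permit
#' and there are no ties (R's ks.test convention); ties force an approximate
#' p-value, flagged in the result. Gaussian-kernel KDEs with Silverman's
#' bandwidth are evaluated on a shared grid and renormalized so their
#' trapezoidal integral over the grid is exactly 1.
#'
#' @param a,b numeric samples, each of size >= 5.
#' @param gridN number of KDE grid points.
#' @return a [DistributionComparison-class].
#' @export
compareDistributions <- function(a, b, gridN = 512L) {
  if (length(a) < 5L || length(b) < 5L)
    stop("each sample needs at least 5 values")
  tied <- FALSE
  kt <- withCallingHandlers(
    stats::ks.test(a, b),
    warning = function(w) {
      if (grepl("ties", conditionMessage(w))) tied <<- TRUE
      invokeRestart("muffleWarning")
    })
  exact <- (as.double(length(a)) * length(b) < 10000) && !tied
  bwA <- stats::bw.nrd0(a); bwB <- stats::bw.nrd0(b)
  lo <- min(a, b) - 4 * max(bwA, bwB)
  hi <- max(a, b) + 4 * max(bwA, bwB)
  grid <- seq(lo, hi, length.out = gridN)
  kde <- function(x, bw) {
    d <- stats::density(x, bw = bw, from = lo, to = hi, n = gridN)$y
    area <- sum((d[-1L] + d[-gridN]) / 2 * diff(grid))
    d / area
  }
  new("DistributionComparison",
      ksStatistic = unname(kt$statistic), pValue = kt$p.value,
      exact = exact, approximate = tied,
      kdeGrid = grid, kdeA = kde(a, bwA), kdeB = kde(b, bwB))
}
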