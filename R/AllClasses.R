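#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core S4 containers. Images are plain numeric matrices indexed 0-based
## (row, col) in pixel units; physical units enter only through pixel_size
## (micrometres per pixel). All lengths are micrometres, times minutes.
## ---------------------------------------------------------------------------

#' IntensityProfile: fluorescence intensity sampled along a geometric path
#'
#' Positions `s` are arclength in micrometres, strictly increasing from 0;
#' `intensity` is in arbitrary units. A cyclic profile (sampled around a
#' closed cell contour) sets `cyclic = TRUE`, meaning the first and last
#' samples are adjacent on the path.
#'
#' @slot s numeric, positions along the path (um), strictly increasing from 0.
#' @slot intensity numeric, intensity values (a.u.), same length as `s`.
#' @slot sourceId character scalar identifying the image/segment of origin.
#' @slot cyclic logical scalar; TRUE for closed-contour profiles.
#' @exportClass IntensityProfile
setClass("IntensityProfile",
  representation(s = "numeric", intensity = "numeric",
                 sourceId = "character", cyclic = "logical"),
  prototype(sourceId = "", cyclic = FALSE))

setValidity("IntensityProfile", function(object) {
  msg <- character()
  if (length(object@s) != length(object@intensity))
    msg <- c(msg, "s and intensity must have equal length")
  if (length(object@s) < 2L)
    msg <- c(msg, "a profile needs at least 2 samples")
  if (length(object@s) >= 2L) {
    if (any(diff(object@s) <= 0)) msg <- c(msg, "s must be strictly increasing")
    if (abs(object@s[1L]) > 1e-12) msg <- c(msg, "s must start at 0")
    if (max(object@s) <= 0) msg <- c(msg, "profile length must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityProfile
#'
#' @param s positions along the path (um), strictly increasing from 0.
#' @param intensity intensity values (a.u.).
#' @param sourceId identifier of the originating image/segment.
#' @param cyclic TRUE when the profile runs around a closed contour.
#' @return an [IntensityProfile-class] object.
#' @export
IntensityProfile <- function(s, intensity, sourceId = "", cyclic = FALSE) {
  new("IntensityProfile", s = as.numeric(s), intensity = as.numeric(intensity),
      sourceId = as.character(sourceId), cyclic = isTRUE(cyclic))
}

#' @describeIn IntensityProfile-class physical length of the profile (um).
#' @param x an IntensityProfile.
#' @export
profileLength <- function(x) {
  stopifnot(is(x, "IntensityProfile"))
  max(x@s)
}

#' ContactRegion: a constant-gap cell-cell segment with its counted contacts
#'
#' @slot regionId character identifier.
#' @slot profile the [IntensityProfile-class] sampled along the segment.
#' @slot cellGapUm constant cell-cell distance for the segment (um).
#' @slot nContacts number of detected contacts.
#' @slot peakPositions contact positions along the profile (um).
#' @slot density contacts per micrometre, `nContacts / profileLength`.
#' @exportClass ContactRegion
setClass("ContactRegion",
  representation(regionId = "character", profile = "IntensityProfile",
                 cellGapUm = "numeric", nContacts = "integer",
                 peakPositions = "numeric", density = "numeric"))

setValidity("ContactRegion", function(object) {
  msg <- character()
  if (object@cellGapUm < 0) msg <- c(msg, "cellGapUm must be >= 0")
  if (object@nContacts < 0L) msg <- c(msg, "nContacts must be >= 0")
  if (length(object@peakPositions) != object@nContacts)
    msg <- c(msg, "peakPositions length must equal nContacts")
  L <- max(object@profile@s)
  if (abs(object@density - object@nContacts / L) > 1e-12 * max(1, object@density))
    msg <- c(msg, "density must equal nContacts / profile length")
  if (length(msg)) msg else TRUE
})

#' CellPerimeterProfile: intensity around a closed cell contour
#'
#' @slot cellId character identifier.
#' @slot profile cyclic [IntensityProfile-class] along the contour.
#' @slot perimeterUm polygonal contour length (um).
#' @slot nFilopodia number of detected filopodia peaks.
#' @slot filopodiaPositions peak positions along the contour (um).
#' @slot filopodiaDensity peaks per micrometre of perimeter.
#' @exportClass CellPerimeterProfile
setClass("CellPerimeterProfile",
  representation(cellId = "character", profile = "IntensityProfile",
                 perimeterUm = "numeric", nFilopodia = "integer",
                 filopodiaPositions = "numeric", filopodiaDensity = "numeric"))

setValidity("CellPerimeterProfile", function(object) {
  msg <- character()
  if (!object@profile@cyclic) msg <- c(msg, "perimeter profile must be cyclic")
  if (object@perimeterUm <= 0) msg <- c(msg, "perimeterUm must be > 0")
  if (abs(object@filopodiaDensity - object@nFilopodia / object@perimeterUm) >
      1e-12 * max(1, object@filopodiaDensity))
    msg <- c(msg, "filopodiaDensity must equal nFilopodia / perimeterUm")
  if (length(msg)) msg else TRUE
})

#' TrajectorySet: time-stamped 2-D cell paths at uniform frame interval
#'
#' @slot data data.frame with columns cell_id, t_min, x_um, y_um.
#' @slot dt frame interval (min), shared by all trajectories.
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(data = "data.frame", dt = "numeric"))

setValidity("TrajectorySet", function(object) {
  d <- object@data
  need <- c("cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(d)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  if (object@dt <= 0) return("dt must be > 0")
  for (id in unique(d$cell_id)) {
    t <- d$t_min[d$cell_id == id]
    if (length(t) < 2L) return("each trajectory needs >= 2 points")
    dtv <- diff(t)
    if (any(dtv <= 0)) return("t_min must be strictly increasing per cell")
    if (any(abs(dtv - object@dt) > 1e-9 * object@dt))
      return("t_min spacing must equal dt for every trajectory")
  }
  TRUE
})

#' Construct a TrajectorySet from a long-format table
#'
#' @param data data.frame with columns cell_id, t_min, x_um, y_um (such as an
#'   export from Fiji's cell-tracking plugin).
#' @param dt frame interval in minutes; inferred from the first trajectory
#'   when omitted.
#' @return a [TrajectorySet-class].
#' @export
TrajectorySet <- function(data, dt = NULL) {
  data <- as.data.frame(data)
  if (is.null(dt)) {
    t1 <- data$t_min[data$cell_id == data$cell_id[1L]]
    if (length(t1) < 2L) stop("cannot infer dt from a single-point trajectory")
    dt <- diff(t1)[1L]
  }
  new("TrajectorySet", data = data, dt = as.numeric(dt))
}

#' MSDCurve: ensemble mean-squared displacement versus lag time
#'
#' @slot lag lag times (min), starting at 0.
#' @slot msd mean squared displacement per lag (um^2).
#' @slot sem standard error of the mean across trajectories (um^2).
#' @slot nTraj number of trajectories contributing per lag.
#' @exportClass MSDCurve
setClass("MSDCurve",
  representation(lag = "numeric", msd = "numeric", sem = "numeric",
                 nTraj = "integer"))

setValidity("MSDCurve", function(object) {
  msg <- character()
  n <- length(object@lag)
  if (length(object@msd) != n || length(object@sem) != n ||
      length(object@nTraj) != n)
    msg <- c(msg, "lag, msd, sem, nTraj must have equal length")
  if (n > 0 && (object@lag[1L] != 0 || object@msd[1L] != 0))
    msg <- c(msg, "msd(0) must be 0 at lag 0")
  if (n > 1 && any(diff(object@nTraj) > 0L))
    msg <- c(msg, "nTraj must be non-increasing with lag")
  if (length(msg)) msg else TRUE
})

#' FilamentSet: digitised filament backbones
#'
#' @slot data data.frame with columns filament_id, x_um, y_um in point order.
#' @exportClass FilamentSet
setClass("FilamentSet", representation(data = "data.frame"))

setValidity("FilamentSet", function(object) {
  need <- c("filament_id", "x_um", "y_um")
  if (!all(need %in% names(object@data)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' Construct a FilamentSet
#' @param data data.frame with columns filament_id, x_um, y_um (point order =
#'   row order within each filament).
#' @return a [FilamentSet-class].
#' @export
FilamentSet <- function(data) new("FilamentSet", data = as.data.frame(data))

#' FilamentShape: arclength-resampled filament with tangent angles
#'
#' @slot points two-column matrix of resampled (x, y) positions (um).
#' @slot s arclength midpoints at which tangent angles are defined (um).
#' @slot theta unwrapped tangent angles (rad) versus `s`.
#' @slot L total contour length after resampling (um).
#' @exportClass FilamentShape
setClass("FilamentShape",
  representation(points = "matrix", s = "numeric", theta = "numeric",
                 L = "numeric"))

#' ModeSpectrum: Fourier tangent-angle mode amplitudes and their variance
#'
#' @slot modes mode numbers (n >= 1).
#' @slot q wavenumbers q_n = n * pi / L (1/um).
#' @slot amplitudes filaments x modes matrix of amplitudes.
#' @slot variance unbiased ensemble variance per mode.
#' @slot L mean contour length of the batch (um).
#' @exportClass ModeSpectrum
setClass("ModeSpectrum",
  representation(modes = "integer", q = "numeric", amplitudes = "matrix",
                 variance = "numeric", L = "numeric"))

setValidity("ModeSpectrum", function(object) {
  msg <- character()
  if (nrow(object@amplitudes) < 2L)
    msg <- c(msg, "ensemble variance needs >= 2 filaments")
  if (any(object@variance < 0)) msg <- c(msg, "variance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' LpFit: persistence length from an inverse-square-law fit
#'
#' The fitted model is `var(a(q)) = (1/Lp) * (1/q^2)`.
#'
#' @slot lpStar effective persistence length (um); NA when the fit failed.
#' @slot fitSe standard error of lpStar (um).
#' @slot modesUsed mode numbers entering the fit.
#' @slot residuals fit residuals per mode.
#' @slot converged TRUE for a successful fit (positive amplitude coefficient).
#' @exportClass LpFit
setClass("LpFit",
  representation(lpStar = "numeric", fitSe = "numeric", modesUsed = "integer",
                 residuals = "numeric", converged = "logical"))

#' LabeledField: a binarized field with connected-component labels
#'
#' @slot mask logical matrix (foreground = TRUE).
#' @slot labels integer matrix; 0 = background, objects numbered from 1.
#' @slot objects data.frame with one row per object: label, row, col
#'   (0-based centroid, px), area_px, centroid_x_um, centroid_y_um,
#'   equivalent_radius_um.
#' @slot pixelSize micrometres per pixel.
#' @slot connectivity 4 or 8.
#' @slot meta list recording the binarization method/threshold.
#' @exportClass LabeledField
setClass("LabeledField",
  representation(mask = "matrix", labels = "matrix", objects = "data.frame",
                 pixelSize = "numeric", connectivity = "integer",
                 meta = "list"),
  prototype(meta = list()))

setValidity("LabeledField", function(object) {
  msg <- character()
  nlab <- if (length(object@labels)) max(object@labels) else 0L
  if (nrow(object@objects) != nlab)
    msg <- c(msg, "object table must have one row per label")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' NeighborDistances: first-neighbor distances of labeled objects
#'
#' @slot distances per-object first-neighbor centroid distance (um).
#' @slot normalized distances divided by the mean equivalent cell radius.
#' @slot meanRadius the normalization divisor (um).
#' @slot allPairs full centroid distance matrix (um) or a 0x0 matrix.
#' @exportClass NeighborDistances
setClass("NeighborDistances",
  representation(distances = "numeric", normalized = "numeric",
                 meanRadius = "numeric", allPairs = "matrix"))

#' DistributionComparison: two-sample KS test plus KDE curves
#'
#' @slot ksStatistic sup-difference of the two empirical CDFs, in [0, 1].
#' @slot pValue two-sample KS p-value.
#' @slot exact TRUE when the exact null distribution was used.
#' @slot approximate TRUE when ties forced an approximate p-value.
#' @slot kdeGrid shared evaluation grid for the two KDE curves.
#' @slot kdeA,kdeB Gaussian-kernel density estimates (Silverman bandwidth),
#'   renormalized so the trapezoidal integral over the grid is exactly 1.
#' @exportClass DistributionComparison
setClass("DistributionComparison",
  representation(ksStatistic = "numeric", pValue = "numeric",
                 exact = "logical", approximate = "logical",
                 kdeGrid = "numeric", kdeA = "numeric", kdeB = "numeric"))

#' DensityBinSummary: binned mean/SEM of contact density versus cell gap
#'
#' @slot binEdges bin edges on the gap axis (um), Freedman-Diaconis width.
#' @slot meanDensity per-bin mean density (contacts/um); NA for empty bins.
#' @slot semDensity per-bin standard error of the mean; NA where n < 2.
#' @slot nPerBin number of regions per bin.
#' @slot binWidth the Freedman-Diaconis width used (um).
#' @slot singleBinFallback TRUE when a zero IQR forced a single bin.
#' @exportClass DensityBinSummary
setClass("DensityBinSummary",
  representation(binEdges = "numeric", meanDensity = "numeric",
                 semDensity = "numeric", nPerBin = "integer",
                 binWidth = "numeric", singleBinFallback = "logical"))

#' GroupComparison: per-group summaries and pairwise two-sample tests
#'
#' Boxplot-style summaries per group (mean, median, 5th and 95th percentile
#' whiskers under the linear-interpolation percentile convention) plus
#' pairwise Mann-Whitney or KS tests.
#'
#' @slot summaries data.frame: group, n, mean, median, p5, p95.
#' @slot tests data.frame: group_a, group_b, test, statistic, p_value.
#' @slot testName "mann_whitney" or "ks".
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(summaries = "data.frame", tests = "data.frame",
                 testName = "character"))

#' InteractionNetwork: gene-symbol nodes with typed undirected edges
#'
#' Edge types come from the closed vocabulary physical, genetic,
#' colocalization, shared_domain, pathway, predicted. Self-loops are
#' disallowed; edges are undirected (stored with from < to).
#'
#' @slot nodes character vector of node (gene symbol) names.
#' @slot edges data.frame with columns from, to, type.
#' @slot nodeDomains named list mapping node -> character vector of domains.
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  representation(nodes = "character", edges = "data.frame",
                 nodeDomains = "list"),
  prototype(nodeDomains = list()))

#' Edge-type vocabulary for [InteractionNetwork-class] objects
#' @export
edgeTypeVocabulary <- function() {
  c("physical", "genetic", "colocalization", "shared_domain",
    "pathway", "predicted")
}

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "type") %in% names(e)))
    return("edges must have columns from, to, type")
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    bad <- setdiff(unique(e$type), edgeTypeVocabulary())
    if (length(bad))
      msg <- c(msg, paste("unknown edge type(s):", paste(bad, collapse = ", ")))
    miss <- setdiff(unique(c(e$from, e$to)), object@nodes)
    if (length(miss))
      msg <- c(msg, paste("edge endpoints missing from nodes:",
                          paste(miss, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork
#'
#' @param nodes character vector of node names (gene symbols).
#' @param edges data.frame with columns from, to, type; undirected, stored
#'   canonically with from < to, duplicate (from, to, type) rows collapsed.
#' @param nodeDomains optional named list of protein-domain annotations.
#' @return an [InteractionNetwork-class].
#' @export
InteractionNetwork <- function(nodes = character(),
                               edges = data.frame(from = character(),
                                                  to = character(),
                                                  type = character()),
                               nodeDomains = list()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- unique(edges[, c("from", "to", "type")])
    edges <- edges[order(edges$from, edges$to, edges$type), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  new("InteractionNetwork", nodes = nodes, edges = edges,
      nodeDomains = nodeDomains)
}

#' DomainInteractionMap: symmetric catalogue of interacting domain pairs
#'
#' @slot pairs data.frame with columns domain_a, domain_b; the symmetric
#'   closure is stored (a-b implies b-a; a-a pairs allowed, covering e.g.
#'   LIM-LIM).
#' @exportClass DomainInteractionMap
setClass("DomainInteractionMap", representation(pairs = "data.frame"))

#' Construct a DomainInteractionMap
#' @param pairs data.frame (or two-column matrix) of interacting domain pairs.
#' @return a [DomainInteractionMap-class] holding the symmetric closure.
#' @export
DomainInteractionMap <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop("'pairs' needs two columns of domain identifiers")
  names(pairs)[1:2] <- c("domain_a", "domain_b")
  a <- as.character(pairs$domain_a); b <- as.character(pairs$domain_b)
  full <- unique(data.frame(domain_a = c(a, b), domain_b = c(b, a),
                            stringsAsFactors = FALSE))
  full <- full[order(full$domain_a, full$domain_b), , drop = FALSE]
  rownames(full) <- NULL
  new("DomainInteractionMap", pairs = full)
}

#' LineSegment: a straight profile path in pixel coordinates
#'
#' Endpoints are 0-based (row, col) pixel positions; intensity is averaged
#' over `widthPx` parallel lines perpendicular to the path.
#'
#' @slot p0,p1 numeric length-2 (row, col) endpoints, 0-based.
#' @slot widthPx perpendicular averaging width in pixels (>= 1).
#' @exportClass LineSegment
setClass("LineSegment",
  representation(p0 = "numeric", p1 = "numeric", widthPx = "numeric"))

setValidity("LineSegment", function(object) {
  msg <- character()
  if (length(object@p0) != 2L || length(object@p1) != 2L)
    msg <- c(msg, "p0 and p1 must be length-2 (row, col)")
  if (identical(object@p0, object@p1)) msg <- c(msg, "p0 must differ from p1")
  if (object@widthPx < 1) msg <- c(msg, "widthPx must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a LineSegment
#' @param p0,p1 0-based (row, col) endpoints.
#' @param widthPx perpendicular averaging width in pixels.
#' @return a [LineSegment-class].
#' @export
LineSegment <- function(p0, p1, widthPx = 1) {
  new("LineSegment", p0 = as.numeric(p0), p1 = as.numeric(p1),
      widthPx = as.numeric(widthPx))
}

## show methods ---------------------------------------------------------------

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile '%s': %d samples over %.3g um%s\n",
              object@sourceId, length(object@s), max(object@s),
              if (object@cyclic) " (cyclic)" else ""))
})

setMethod("show", "ContactRegion", function(object) {
  cat(sprintf(
    "ContactRegion '%s': gap %.3g um, %d contacts over %.3g um (%.4g /um)\n",
    object@regionId, object@cellGapUm, object@nContacts,
    max(object@profile@s), object@density))
})

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf("TrajectorySet: %d trajectories, dt = %g min\n",
              length(unique(object@data$cell_id)), object@dt))
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve: %d lags up to %g min, %d trajectories at lag 1\n",
              length(object@lag), max(object@lag),
              if (length(object@nTraj) > 1L) object@nTraj[2L] else 0L))
})

setMethod("show", "ModeSpectrum", function(object) {
  cat(sprintf("ModeSpectrum: modes %s over %d filaments (L = %.3g um)\n",
              paste(range(object@modes), collapse = "-"),
              nrow(object@amplitudes), object@L))
})

setMethod("show", "LpFit", function(object) {
  if (object@converged) {
    cat(sprintf("LpFit: Lp* = %.4g um (se %.3g), modes %s\n",
                object@lpStar, object@fitSe,
                paste(range(object@modesUsed), collapse = "-")))
  } else {
    cat("LpFit: fit failed (non-positive amplitude coefficient)\n")
  }
})

setMethod("show", "LabeledField", function(object) {
  cat(sprintf("LabeledField: %d objects (connectivity %d, %g um/px)\n",
              nrow(object@objects), object@connectivity, object@pixelSize))
})

setMethod("show", "InteractionNetwork", function(object) {
  tt <- table(object@edges$type)
  cat(sprintf("InteractionNetwork: %d nodes, %d edges (%s)\n",
              length(object@nodes), nrow(object@edges),
              if (length(tt)) paste(names(tt), tt, sep = ": ", collapse = ", ")
              else "no edges"))
})

## small accessors ------------------------------------------------------------

#' Number of contacts in a ContactRegion
#' @param x a [ContactRegion-class].
#' @return integer count.
#' @export
nContacts <- function(x) { stopifnot(is(x, "ContactRegion")); x@nContacts }

#' Object table of a LabeledField
#' @param x a [LabeledField-class].
#' @return data.frame of per-object centroids, areas and equivalent radii.
#' @export
objectTable <- function(x) { stopifnot(is(x, "LabeledField")); x@objects }

#' MSD curve as a data.frame
#' @param x an [MSDCurve-class].
#' @return data.frame with columns lag, msd, sem, n_traj.
#' @export
msdTable <- function(x) {
  stopifnot(is(x, "MSDCurve"))
  data.frame(lag = x@lag, msd = x@msd, sem = x@sem, n_traj = x@nTraj)
}

#' Edges of an InteractionNetwork
#' @param x an [InteractionNetwork-class].
#' @return data.frame with columns from, to, type.
#' @export
networkEdges <- function(x) { stopifnot(is(x, "InteractionNetwork")); x@edges }

#' Nodes of an InteractionNetwork
#' @param x an [InteractionNetwork-class].
#' @return character vector of node names.
#' @export
networkNodes <- function(x) { stopifnot(is(x, "InteractionNetwork")); x@nodes }
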