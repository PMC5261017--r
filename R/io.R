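## File I/O: single-channel TIFF images (float, with a JSON sidecar restoring
## the original intensity range when normalization was needed) and the CSV
## table formats used by the pipeline.

#' Write a single-channel image as 32-bit float TIFF
#'
#' TIFF float storage is defined on [0, 1]; images outside that range are
#' affinely rescaled and the original range recorded in a `<path>.json`
#' sidecar, which [readImageTIFF()] uses to restore intensities exactly up to
#' float precision.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImageTIFF <- function(image, path) {
  assertMatrixImage(image)
  rng <- range(image)
  scaled <- image
  if (rng[1L] < 0 || rng[2L] > 1) {
    span <- if (diff(rng) > 0) diff(rng) else 1
    scaled <- (image - rng[1L]) / span
    jsonlite::write_json(list(orig_min = rng[1L], orig_max = rng[2L]),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (file.exists(paste0(path, ".json"))) {
    unlink(paste0(path, ".json"))
  }
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a single-channel TIFF image
#'
#' @param path TIFF path; a `<path>.json` range sidecar written by
#'   [writeImageTIFF()] is applied when present.
#' @return numeric matrix.
#' @export
readImageTIFF <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] != 1L)
      stop("multi-channel TIFF: expected a single-channel image")
    img <- img[, , 1L]
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    rng <- jsonlite::read_json(sidecar)
    span <- rng$orig_max - rng$orig_min
    if (span <= 0) span <- 1
    img <- img * span + rng$orig_min
  }
  img
}

#' Read trajectories from CSV
#' @param path CSV with columns cell_id, t_min, x_um, y_um.
#' @param dt frame interval (min); inferred when NULL.
#' @return a [TrajectorySet-class].
#' @export
readTrajectoryCSV <- function(path, dt = NULL) {
  TrajectorySet(utils::read.csv(path, stringsAsFactors = FALSE), dt = dt)
}

#' Write trajectories to CSV
#' @param trajs a [TrajectorySet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(trajs, path) {
  stopifnot(is(trajs, "TrajectorySet"))
  utils::write.csv(trajs@data, path, row.names = FALSE)
  invisible(path)
}

#' Read filament coordinates from CSV
#'
#' @param path CSV with columns filament_id, x_um, y_um, optionally `order`
#'   (rows are sorted by it within each filament).
#' @return a [FilamentSet-class].
#' @export
readFilamentCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("order" %in% names(d)) {
    d <- d[order(d$filament_id, d$order), , drop = FALSE]
    rownames(d) <- NULL
  }
  FilamentSet(d[, c("filament_id", "x_um", "y_um")])
}

#' Write filament coordinates to CSV
#' @param filaments a [FilamentSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFilamentCSV <- function(filaments, path) {
  stopifnot(is(filaments, "FilamentSet"))
  d <- filaments@data
  d$order <- stats::ave(seq_len(nrow(d)), d$filament_id, FUN = seq_along)
  utils::write.csv(d[, c("filament_id", "order", "x_um", "y_um")], path,
                   row.names = FALSE)
  invisible(path)
}
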