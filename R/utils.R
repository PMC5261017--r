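## Internal helpers shared across modules.

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All generators take an explicit integer seed; sub-streams are derived
#' deterministically from it so a generator is a pure function of its
#' parameters.
#'
#' @param seed single finite integer-like value.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## scalar validators ---------------------------------------------------------

assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("'%s' must be > %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("'%s' must be >= %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("'%s' must be <= %g (got %g)", name, upper, x), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be an integer (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

assertMatrixImage <- function(image, name = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("'%s' must be a numeric matrix (single-channel image)", name),
         call. = FALSE)
  }
  invisible(image)
}

## bilinear interpolation at fractional 0-based (row, col) positions ---------
## Out-of-range queries are an error; callers validate bounds first.
bilinearAt <- function(image, row, col) {
  nr <- nrow(image); nc <- ncol(image)
  # clamp to the valid interpolation domain [0, n-1]
  row <- pmin(pmax(row, 0), nr - 1L)
  col <- pmin(pmax(col, 0), nc - 1L)
  r0 <- floor(row); c0 <- floor(col)
  r0 <- pmin(r0, nr - 2L); c0 <- pmin(c0, nc - 2L)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- row - r0; fc <- col - c0
  i00 <- image[cbind(r0 + 1L, c0 + 1L)]
  i01 <- image[cbind(r0 + 1L, c0 + 2L)]
  i10 <- image[cbind(r0 + 2L, c0 + 1L)]
  i11 <- image[cbind(r0 + 2L, c0 + 2L)]
  i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
    i10 * fr * (1 - fc) + i11 * fr * fc
}

## Freedman-Diaconis bin width ------------------------------------------------

#' Freedman-Diaconis bin width
#'
#' Computes the histogram bin width `h = 2 * IQR(x) * n^(-1/3)` used for all
#' binned summaries in the package. Quartiles use the linear-interpolation
#' convention (`stats::quantile` type 7).
#'
#' @param x numeric vector of values to be binned.
#' @return the bin width (same units as `x`); zero when the IQR is zero.
#' @examples
#' fdBinWidth(rep(c(1, 3, 5, 7), each = 16)) # n = 64, IQR = 4 -> 2.0
#' @export
fdBinWidth <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 finite values for a bin width")
  2 * stats::IQR(x, type = 7) * n^(-1 / 3)
}

## quantile convention used for boxplot whiskers (linear interpolation)
pctile <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

## deterministic md5 of a file (used by the pipeline manifest)
fileChecksum <- function(path) unname(tools::md5sum(path))
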