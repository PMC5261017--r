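## Ensemble mean-squared displacement and explored-area summaries for
## wound-healing cell trajectories.

#' ExploredArea: per-trajectory maximum displacement radius within a horizon
#'
#' @slot radii per-trajectory maximum displacement from the starting point
#'   within the horizon (um).
#' @slot meanRadius mean radius (um).
#' @slot semRadius standard error of the mean radius (um).
#' @slot horizon time horizon (min).
#' @exportClass ExploredArea
setClass("ExploredArea",
  representation(radii = "numeric", meanRadius = "numeric",
                 semRadius = "numeric", horizon = "numeric"))

setMethod("show", "ExploredArea", function(object) {
  cat(sprintf("ExploredArea: mean radius %.4g um (se %.3g) after %g min, %d trajectories\n",
              object@meanRadius, object@semRadius, object@horizon,
              length(object@radii)))
})

## split a TrajectorySet into per-cell coordinate matrices, preserving order
splitTrajectories <- function(trajs) {
  d <- trajs@data
  lapply(split(d[, c("t_min", "x_um", "y_um")], d$cell_id), as.matrix)
}

#' Ensemble mean-squared displacement
#'
#' `MSD(tau) = < (x(t0 + tau) - x(t0))^2 + (y(t0 + tau) - y(t0))^2 >`, where
#' t0 is each trajectory's first frame and the angle brackets average over the
#' trajectory ensemble (pure ensemble average, no time averaging; a
#' time-averaged variant is available via `timeAverage = TRUE`, clearly
#' non-default). SEM is the standard error across trajectories per lag.
#'
#' @param trajs a [TrajectorySet-class] (uniform dt enforced by the class).
#' @param maxLag largest lag (min); defaults to the shortest trajectory
#'   duration and may not exceed it.
#' @param timeAverage use the time-averaged MSD per trajectory before the
#'   ensemble average (non-default robustness variant).
#' @return an [MSDCurve-class] including lag 0.
#' @examples
#' tr <- simulateTrajectories(nTraj = 50, nSteps = 30, dt = 20, D = 1, seed = 1)
#' msd <- computeMSD(tr)
#' @export
computeMSD <- function(trajs, maxLag = NULL, timeAverage = FALSE) {
  if (is.data.frame(trajs)) trajs <- TrajectorySet(trajs)
  stopifnot(is(trajs, "TrajectorySet"))
  parts <- splitTrajectories(trajs)
  if (!length(parts)) stop("empty trajectory set")
  dt <- trajs@dt
  shortest <- min(vapply(parts, nrow, integer(1L))) - 1L  # steps
  if (is.null(maxLag)) maxLag <- shortest * dt
  kmax <- as.integer(floor(maxLag / dt + 1e-9))
  if (kmax < 1L) stop("maxLag must cover at least one frame interval")
  if (kmax > shortest)
    stop("maxLag exceeds the shortest trajectory duration")
  nT <- length(parts)
  sq <- matrix(NA_real_, nT, kmax)  # per-trajectory squared displacement
  for (i in seq_len(nT)) {
    m <- parts[[i]]
    x <- m[, "x_um"]; y <- m[, "y_um"]
    if (timeAverage) {
      np <- length(x)
      sq[i, ] <- vapply(seq_len(kmax), function(k) {
        j <- seq_len(np - k)
        mean((x[j + k] - x[j])^2 + (y[j + k] - y[j])^2)
      }, numeric(1L))
    } else {
      k <- seq_len(kmax)
      sq[i, ] <- (x[1L + k] - x[1L])^2 + (y[1L + k] - y[1L])^2
    }
  }
  msd <- colMeans(sq)
  sem <- apply(sq, 2L, stats::sd) / sqrt(nT)
  new("MSDCurve", lag = c(0, seq_len(kmax) * dt), msd = c(0, msd),
      sem = c(0, sem), nTraj = rep(nT, kmax + 1L))
}

#' Fit a diffusion law to an MSD curve
#'
#' Linear model: ordinary least squares of MSD on lag; the diffusion
#' coefficient is slope / 4 (2-D). Power model: least squares of log(MSD) on
#' log(lag), giving the anomalous exponent alpha and prefactor; non-positive
#' MSD values are excluded and reported.
#'
#' @param curve an [MSDCurve-class].
#' @param model "linear" or "power".
#' @param lagRange optional (min, max) lag window (min); lag 0 never enters.
#' @return a list: for "linear", `D`, `DSe`, `slope`, `intercept`; for
#'   "power", `alpha`, `alphaSe`, `prefactor`; both include `model`,
#'   `lagsUsed` and `excludedLags`.
#' @export
fitMSD <- function(curve, model = c("linear", "power"), lagRange = NULL) {
  stopifnot(is(curve, "MSDCurve"))
  model <- match.arg(model)
  lag <- curve@lag; msd <- curve@msd
  sel <- lag > 0
  if (!is.null(lagRange)) sel <- sel & lag >= lagRange[1L] & lag <= lagRange[2L]
  excluded <- numeric()
  if (model == "power") {
    bad <- sel & msd <= 0
    excluded <- lag[bad]
    sel <- sel & msd > 0
  }
  if (sum(sel) < 3L) stop("need at least 3 lags in the fit range")
  if (model == "linear") {
    fit <- stats::lm(msd[sel] ~ lag[sel])
    co <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
    list(model = "linear", D = co[2L, 1L] / 4, DSe = co[2L, 2L] / 4,
         slope = co[2L, 1L], intercept = co[1L, 1L],
         lagsUsed = lag[sel], excludedLags = excluded)
  } else {
    fit <- stats::lm(log(msd[sel]) ~ log(lag[sel]))
    co <- suppressWarnings(summary(fit))$coefficients
    list(model = "power", alpha = co[2L, 1L], alphaSe = co[2L, 2L],
         prefactor = exp(co[1L, 1L]),
         lagsUsed = lag[sel], excludedLags = excluded)
  }
}

#' Explored area (maximum displacement radius) within a time horizon
#'
#' Operationalizes the "mean area explored" as the per-trajectory maximum
#' displacement from the starting point within the horizon (the radius of the
#' dashed circle around each start point), averaged over trajectories.
#'
#' @param trajs a [TrajectorySet-class].
#' @param horizon time horizon (min); must not exceed any trajectory's
#'   duration.
#' @return an [ExploredArea-class].
#' @export
exploredArea <- function(trajs, horizon) {
  if (is.data.frame(trajs)) trajs <- TrajectorySet(trajs)
  stopifnot(is(trajs, "TrajectorySet"))
  assertScalar(horizon, "horizon", 0, strict_lower = TRUE)
  parts <- splitTrajectories(trajs)
  radii <- vapply(parts, function(m) {
    t0 <- m[1L, "t_min"]
    if (horizon > max(m[, "t_min"]) - t0 + 1e-9)
      stop("horizon exceeds a trajectory's duration")
    keep <- m[, "t_min"] - t0 <= horizon + 1e-9
    max(sqrt((m[keep, "x_um"] - m[1L, "x_um"])^2 +
             (m[keep, "y_um"] - m[1L, "y_um"])^2))
  }, numeric(1L))
  new("ExploredArea", radii = unname(radii), meanRadius = mean(radii),
      semRadius = stats::sd(radii) / sqrt(length(radii)),
      horizon = horizon)
}
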