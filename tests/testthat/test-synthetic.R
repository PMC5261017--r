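# Synthetic-data generators: determinism, ground-truth conservation and
# statistical calibration against closed forms.

test_that("zero-contact noise-free scene has a flat inter-cell profile", {
  sc <- simulateContactScene(contactsPerRegion = 0, noiseSd = 0, seed = 1)
  prof <- extractProfile(sc$image, sceneSegments(sc, widthPx = 1)[[1]],
                         sc$pixelSize)
  expect_true(all(abs(prof@intensity - sc$params$background) < 1e-12))
})

test_that("rendered contacts appear as local maxima of the midline row", {
  sc <- simulateContactScene(contactsPerRegion = 5, noiseSd = 0, seed = 2)
  reg <- sc$truth$regions
  # exhaustive scan of the rendered array along the midline (oracle)
  rowIdx <- round(reg$row_px[1]) + 1L
  y <- sc$image[rowIdx, (reg$x0_px[1]:reg$x1_px[1]) + 1L]
  peaks <- bruteLocalMaxima(y)
  peaks <- peaks[y[peaks] > sc$params$background + 0.5 * sc$params$peakAmplitude]
  expect_identical(length(peaks), 5L)
  expect_identical(nrow(sc$truth$contacts), 5L)
})

test_that("scene generation is deterministic and leaves the RNG alone", {
  set.seed(99); before <- .Random.seed
  a <- simulateContactScene(contactsPerRegion = 4, noiseSd = 0.2, seed = 7)
  expect_identical(.Random.seed, before)
  b <- simulateContactScene(contactsPerRegion = 4, noiseSd = 0.2, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$contacts, b$truth$contacts)
})

test_that("unplaceable contact requests are rejected with a clear message", {
  expect_error(
    simulateContactScene(contactsPerRegion = 40, regionLengthUm = 10,
                         peakWidthUm = 0.7, seed = 1),
    "cannot place")
})

test_that("ground-truth contact separations respect twice the peak width", {
  for (s in 1:10) {
    sc <- simulateContactScene(contactsPerRegion = 8, seed = s)
    gaps <- diff(sort(sc$truth$contacts$s_um))
    expect_true(all(gaps >= 2 * sc$params$peakWidthUm - 1e-9))
  }
})

test_that("frozen trajectories (D = 0) have zero MSD at all lags", {
  tr <- simulateTrajectories(nTraj = 5, nSteps = 10, dt = 20, D = 0, seed = 1)
  msd <- computeMSD(tr)
  expect_true(all(msd@msd == 0))
})

test_that("Brownian steps match the 4*D*dt closed form within 3 SE", {
  tr <- simulateTrajectories(nTraj = 1000, nSteps = 10, dt = 20, D = 1,
                             seed = 3)
  d <- tr@data
  steps <- do.call(rbind, lapply(split(d, d$cell_id), function(f) {
    cbind(diff(f$x_um), diff(f$y_um))
  }))
  sq <- steps[, 1]^2 + steps[, 2]^2
  se <- stats::sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - 4 * 1 * 20), 3 * se)
})

test_that("persistent walkers start superdiffusive relative to matched steps", {
  brown <- computeMSD(simulateTrajectories(400, 40, dt = 20, D = 1, seed = 4))
  pers <- computeMSD(simulateTrajectories(400, 40, dt = 20, D = 1,
                                          persistenceTime = 200, seed = 4))
  k <- 3:7  # short lags (lag 1 is seed-identical by construction)
  expect_true(all(pers@msd[k] > brown@msd[k]))
  expect_gt(fitMSD(pers, "power", lagRange = c(20, 120))$alpha, 1.2)
})

test_that("negative D is rejected", {
  expect_error(simulateTrajectories(1, 1, 20, D = -1, seed = 1), "'D'")
})

test_that("rigid-rod limit gives straight filaments with vanishing modes", {
  fs <- simulateWLCFilaments(5, contourLength = 5, lpTrue = 1e9,
                             nPoints = 50, seed = 1)
  sp <- filamentModeSpectrum(fs, nMax = 5)
  expect_true(all(abs(sp@amplitudes) < 1e-3))
})

test_that("WLC end-to-end tangent variance matches L/Lp within 3 SE", {
  n <- 2000
  fs <- simulateWLCFilaments(n, contourLength = 5, lpTrue = 5,
                             nPoints = 50, seed = 2)
  d <- fs@data
  v <- vapply(split(d, d$filament_id), function(f) {
    th <- atan2(diff(f$y_um), diff(f$x_um))
    dw <- diff(th)
    sum(atan2(sin(dw), cos(dw)))    # unwrapped theta(L) - theta(0)
  }, numeric(1))
  # discrete chain accumulates variance over nPoints-2 increments
  expected <- (48 / 49) * 5 / 5
  se <- expected * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(v) - expected), 3 * se)
})

test_that("filament generation is reproducible and rejects bad Lp", {
  a <- simulateWLCFilaments(3, 5, 10, 20, seed = 9)
  b <- simulateWLCFilaments(3, 5, 10, 20, seed = 9)
  expect_identical(a@data, b@data)
  expect_error(simulateWLCFilaments(3, 5, lpTrue = 0, 20, seed = 1), "lpTrue")
})

test_that("disjoint rendered disks give one component per truth center", {
  pp <- simulatePointPattern(fieldSize = c(200, 200), intensity = 3e-4,
                             meanCellRadius = 3, pixelSize = 1, seed = 1)
  n <- nrow(pp$truth)
  expect_gt(n, 0L)
  dmin <- min(stats::dist(pp$truth[, c("x_um", "y_um")]))
  expect_gt(dmin, 2 * max(pp$truth$r_um) + 2 * pp$pixelSize) # truly disjoint
  field <- labelComponents(pp$mask, pixelSize = pp$pixelSize)
  expect_identical(nrow(objectTable(field)), n)
})

test_that("radius_cv = 0 gives equal radii and high intensity warns", {
  pp <- simulatePointPattern(c(100, 100), 5e-4, meanCellRadius = 2,
                             radiusCv = 0, seed = 1)
  expect_true(all(pp$truth$r_um == 2))
  expect_null(pp$overlapWarning)
  crowded <- simulatePointPattern(c(100, 100), 0.02, meanCellRadius = 4,
                                  seed = 1)
  expect_match(crowded$overlapWarning, "overlap")
})

test_that("DE generator: empty fractions give empty thresholded sets", {
  de <- simulateDETables(nGenes = 200, fracUp = 0, fracDown = 0, seed = 1)
  sets <- thresholdDE(de$tables[[1]])
  expect_true(all(lengths(sets$up) == 0))
  expect_true(all(lengths(sets$down) == 0))
})

test_that("DE truth is recovered at cutoffs below the effect range and not above", {
  de <- simulateDETables(nGenes = 1000, fracUp = 0.1, fracDown = 0,
                         fcMagnitudeRange = c(3, 5), seed = 2)
  sets <- thresholdDE(de$tables[[1]], cutoffs = c(2, 3, 5, 8))
  expect_identical(sets$up[["2"]], de$truth$up)
  expect_identical(sets$up[["3"]], de$truth$up)
  expect_identical(sets$up[["5"]], character(0))
  expect_identical(sets$up[["8"]], character(0))
})

test_that("two planted comparisons overlap exactly on the truth sets", {
  de <- simulateDETables(nGenes = 500, fracUp = 0.05, fracDown = 0.05,
                         twoComparisons = TRUE, seed = 3)
  a <- thresholdDE(de$tables[[1]])
  b <- thresholdDE(de$tables[[2]])
  ov <- overlapComparisons(a, b)
  expect_identical(ov$sets[["2"]]$up_overlap, de$truth$up)
  expect_identical(ov$sets[["2"]]$down_overlap, de$truth$down)
})
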