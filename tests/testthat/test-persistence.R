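# Tangent-angle decomposition, Fourier mode amplitudes, ensemble variance and
# the inverse-square-law persistence-length fit.

test_that("a straight filament has zero tangent angle and zero modes", {
  pts <- cbind(seq(0, 5, length.out = 20), 0)
  sh <- tangentAngles(pts)
  expect_true(all(abs(sh@theta) < 1e-12))
  expect_true(all(abs(fourierModes(sh, 5)) < 1e-12))
})

test_that("a quarter circle has theta linear in s with slope 1/R", {
  R <- 4
  phi <- seq(0, pi / 2, length.out = 100)
  pts <- cbind(R * cos(phi), R * sin(phi))
  sh <- tangentAngles(pts, resampleStep = 0.05)
  fit <- stats::lm(sh@theta ~ sh@s)
  expect_equal(unname(stats::coef(fit)[2]), 1 / R, tolerance = 1e-3)
})

test_that("resampled arclength is within 1% of the polygonal length", {
  set.seed(15)
  for (rep in 1:10) {
    fs <- simulateWLCFilaments(1, 5, lpTrue = 8, nPoints = 40, seed = rep)
    pts <- fs@data[, c("x_um", "y_um")]
    polyLen <- sum(sqrt(rowSums(diff(as.matrix(pts))^2)))
    sh <- tangentAngles(pts)
    expect_lt(abs(sh@L - polyLen) / polyLen, 0.01)
  }
})

test_that("a pure cosine tangent profile loads only mode 1", {
  # build a filament whose tangent angle is exactly c*cos(pi*s/L)
  L <- 6; cAmp <- 0.4; N <- 600
  ds <- L / N
  sMid <- (seq_len(N) - 0.5) * ds
  theta <- cAmp * cos(pi * sMid / L)
  pts <- rbind(c(0, 0), cbind(cumsum(ds * cos(theta)), cumsum(ds * sin(theta))))
  sh <- tangentAngles(pts, resampleStep = ds)
  a <- fourierModes(sh, 4)
  # quadrature oracle for a_1 on the same grid convention
  a1 <- sqrt(2 / L) * stats::integrate(function(s) {
    cAmp * cos(pi * s / L) * cos(pi * s / L)
  }, 0, L)$value
  expect_equal(a[1], a1, tolerance = 0.01)
  expect_equal(a[1], cAmp * sqrt(L / 2), tolerance = 0.01)
  expect_true(all(abs(a[2:4]) < 0.02 * abs(a[1])))
})

test_that("mode amplitudes are invariant under rigid rotation", {
  fs <- simulateWLCFilaments(1, 5, lpTrue = 10, nPoints = 50, seed = 16)
  pts <- as.matrix(fs@data[, c("x_um", "y_um")])
  phi <- 1.1
  rot <- pts %*% rbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
  a0 <- fourierModes(tangentAngles(pts), 5)
  a1 <- fourierModes(tangentAngles(rot), 5)
  expect_equal(a0, a1, tolerance = 1e-8)
})

test_that("self-crossing tangent reversals and aliasing are rejected", {
  pts <- cbind(c(0, 1, 2, 3, 2, 1, 0, -1), rep(0, 8))
  expect_error(tangentAngles(pts), "self-crossing|jump")
  sh <- tangentAngles(cbind(seq(0, 5, length.out = 20), 0))
  expect_error(fourierModes(sh, 50), "aliasing")
  expect_error(tangentAngles(cbind(c(0, 0, 1:6), rep(0, 8))), "duplicate")
})

test_that("ensemble variance: zeros for identical filaments, chi-square for iid", {
  amp <- matrix(rep(c(0.1, -0.2, 0.3), each = 10), 10, 3)
  sp <- ensembleVariance(amp, L = 5)
  expect_true(all(sp@variance == 0))
  set.seed(17)
  sigma <- 0.25
  amp2 <- matrix(stats::rnorm(400 * 3, 0, sigma), 400, 3)
  sp2 <- ensembleVariance(amp2, L = 5)
  se <- sigma^2 * sqrt(2 / 399)
  expect_true(all(abs(sp2@variance - sigma^2) < 3 * se))
  # permutation invariance
  sp3 <- ensembleVariance(amp2[sample(400), ], L = 5)
  expect_equal(sp3@variance, sp2@variance)
  expect_error(ensembleVariance(amp2, L = c(rep(5, 399), 7)), "batches")
})

test_that("an exact inverse-square spectrum inverts to its Lp", {
  L <- 5
  q <- (1:6) * pi / L
  amp <- matrix(0, 2, 6)  # amplitudes unused by the fit itself
  sp <- new("ModeSpectrum", modes = 1:6, q = q, amplitudes = amp,
            variance = (1 / 10) / q^2, L = L)
  fit <- fitPersistenceLength(sp, 1:5)
  expect_true(fit@converged)
  expect_equal(fit@lpStar, 10, tolerance = 1e-10)
  # degenerate: an all-zero spectrum has no positive inverse-square trend
  spBad <- new("ModeSpectrum", modes = 1:6, q = q, amplitudes = amp,
               variance = rep(0, 6), L = L)
  fitBad <- fitPersistenceLength(spBad, 1:5)
  expect_false(fitBad@converged)
  expect_true(is.na(fitBad@lpStar))
  expect_error(fitPersistenceLength(sp, 1:2), "at least 3")
})

test_that("rigid-rod mode variances vanish relative to the flexible case", {
  rigid <- filamentModeSpectrum(
    simulateWLCFilaments(100, 5, lpTrue = 5e3, nPoints = 50, seed = 18), 5)
  floppy <- filamentModeSpectrum(
    simulateWLCFilaments(100, 5, lpTrue = 5, nPoints = 50, seed = 18), 5)
  expect_true(all(rigid@variance < 1e-2 * floppy@variance))
})

test_that("WLC ensembles recover the planted persistence length", {
  fs <- simulateWLCFilaments(500, 5, lpTrue = 10, nPoints = 50, seed = 19)
  fit <- fitPersistenceLength(filamentModeSpectrum(fs, 5), 1:5)
  expect_lt(abs(fit@lpStar - 10) / 10, 0.15)
})

test_that("localization noise biases high modes; modes 1-3 still recover Lp", {
  fs <- simulateWLCFilaments(500, 5, lpTrue = 10, nPoints = 20,
                             localizationNoiseSd = 0.05, seed = 20)
  sp <- filamentModeSpectrum(fs, 8, lengthTol = 0.2)
  # noise inflates variance fastest at high q: the apparent Lp drops
  apparentLp <- 1 / (sp@variance * sp@q^2)
  expect_lt(mean(apparentLp[7:8]), mean(apparentLp[1:3]))
  expect_lt(apparentLp[8], 10)
  fit <- fitPersistenceLength(sp, 1:3)
  expect_lt(abs(fit@lpStar - 10) / 10, 0.20)
})
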