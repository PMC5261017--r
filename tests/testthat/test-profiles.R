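# Profile extraction, peak counting, contact density and constant-gap
# segmentation.

test_that("a constant image yields a flat profile for any segment", {
  img <- matrix(7.5, 40, 60)
  p <- extractProfile(img, LineSegment(c(5, 3), c(30, 50), widthPx = 3), 0.2)
  expect_equal(p@intensity, rep(7.5, length(p@s)), tolerance = 1e-12)
  expect_equal(profileLength(p),
               sqrt(25^2 + 47^2) * 0.2)
})

test_that("horizontal profile on a column gradient matches direct indexing", {
  nc <- 30
  img <- matrix(rep(0:(nc - 1), each = 10), 10, nc)
  p <- extractProfile(img, LineSegment(c(4, 0), c(4, nc - 1)), pixelSize = 1)
  # oracle: the image value at integer column positions
  expect_equal(p@intensity, p@s, tolerance = 1e-12)
  expect_equal(p@intensity, img[5, ], tolerance = 1e-12)
})

test_that("out-of-bounds segments are rejected", {
  img <- matrix(0, 10, 10)
  expect_error(extractProfile(img, LineSegment(c(0, 0), c(0, 20)), 1),
               "out of image bounds")
  expect_error(extractProfile(img, LineSegment(c(0, 0), c(0, 9),
                                               widthPx = 7), 1),
               "out of image bounds")
})

test_that("flat profiles contain zero contacts without error", {
  p <- IntensityProfile(s = seq(0, 10, 0.1), intensity = rep(2, 101))
  expect_identical(countContacts(p)$n, 0L)
})

test_that("seven noise-free bumps are counted exactly at known positions", {
  s <- seq(0, 30, by = 0.05)
  truth <- c(2.5, 6, 10, 13.5, 18, 22, 27)
  y <- 0.1 + Reduce(`+`, lapply(truth, function(m) exp(-(s - m)^2 / (2 * 0.3^2))))
  p <- IntensityProfile(s, y)
  cc <- countContacts(p, peakParams(minProminenceFrac = 0.2))
  expect_identical(cc$n, 7L)
  expect_true(all(abs(cc$positions - truth) <= 0.05 / 2 + 1e-9))
  # independent oracle: exhaustive local-maximum scan of the raw profile
  expect_identical(length(bruteLocalMaxima(y)), 7L)
})

test_that("two bumps closer than the separation keep only the higher", {
  s <- seq(0, 10, by = 0.02)
  y <- exp(-(s - 5)^2 / (2 * 0.15^2)) + 0.8 * exp(-(s - 5.6)^2 / (2 * 0.15^2))
  p <- IntensityProfile(s, y)
  cc <- countContacts(p, peakParams(minSeparationUm = 1, smoothUm = 0))
  expect_identical(cc$n, 1L)
  expect_lt(abs(cc$positions - 5), 0.15)  # the higher bump survives
})

test_that("counts and densities are invariant under intensity scaling", {
  for (s in 1:5) {
    sc <- simulateContactScene(contactsPerRegion = 5, noiseSd = 0.15, seed = s)
    prof <- extractProfile(sc$image, sceneSegments(sc)[[1]], sc$pixelSize)
    scaled <- IntensityProfile(prof@s, prof@intensity * 37.5)
    expect_identical(countContacts(prof), countContacts(scaled))
  }
})

test_that("contact density is the count per unit profile length, exactly", {
  s <- seq(0, 5, by = 0.01)
  y <- 0.1 + Reduce(`+`, lapply(seq(0.25, 4.3, by = 0.45),
                                function(m) exp(-(s - m)^2 / (2 * 0.08^2))))
  reg <- contactRegion(IntensityProfile(s, y), cellGapUm = 2,
                       params = peakParams(minSeparationUm = 0.2,
                                           smoothUm = 0.05))
  expect_identical(nContacts(reg), 10L)
  expect_identical(contactDensity(reg), 2)           # 10 contacts / 5 um
  expect_identical(reg@density * profileLength(reg@profile),
                   as.numeric(nContacts(reg)))        # identity to precision
})

test_that("synthetic regions give density = truth count / length noise-free", {
  for (s in 1:5) {
    k <- s + 2L
    sc <- simulateContactScene(contactsPerRegion = k, noiseSd = 0, seed = s)
    prof <- extractProfile(sc$image, sceneSegments(sc)[[1]], sc$pixelSize)
    reg <- contactRegion(prof, cellGapUm = 2)
    expect_identical(nContacts(reg), k)
    expect_equal(contactDensity(reg), k / profileLength(prof))
  }
})

test_that("constant gap trace yields a single full span", {
  tr <- data.frame(s = seq(0, 10, 0.5), gap = rep(3, 21))
  sp <- segmentConstantGap(tr, tolGap = 0.5)
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$start_idx, 1L)
  expect_identical(sp$end_idx, 21L)
  expect_identical(sp$cell_gap_um, 3)
})

test_that("a gap step splits into exactly two spans at the step", {
  tr <- data.frame(s = 0:9, gap = c(rep(2, 5), rep(8, 5)))
  sp <- segmentConstantGap(tr, tolGap = 1)
  expect_identical(nrow(sp), 2L)
  expect_identical(sp$end_idx[1], 5L)
  expect_identical(sp$start_idx[2], 6L)
  expect_identical(sp$cell_gap_um, c(2, 8))
})

test_that("ramp segmentation matches the brute-force span oracle", {
  set.seed(11)
  for (rep in 1:20) {
    g <- cumsum(stats::runif(60, -0.4, 0.6))
    tr <- data.frame(s = seq_along(g), gap = g)
    sp <- segmentConstantGap(tr, tolGap = 1)
    oracle <- bruteSpans(g, 1)
    expect_identical(cbind(sp$start_idx, sp$end_idx), unname(oracle))
  }
  expect_error(segmentConstantGap(data.frame(s = 1, gap = 1), 1),
               "at least 2 samples")
})

test_that("identical regions fall in one populated bin with zero SEM", {
  prof <- IntensityProfile(seq(0, 5, 0.05),
                           0.1 + exp(-(seq(0, 5, 0.05) - 2.5)^2 / 0.02))
  regs <- replicate(6, contactRegion(prof, cellGapUm = 4), simplify = FALSE)
  bs <- densityVsDistance(regs)
  expect_true(bs@singleBinFallback)
  tab <- binTable(bs)
  expect_identical(tab$n, 6L)
  expect_identical(tab$sem_density, 0)
})

test_that("Freedman-Diaconis width follows 2*IQR*n^(-1/3) exactly", {
  gaps <- (1:64) * (4 / 31.5)         # n = 64 values with IQR exactly 4
  expect_equal(stats::IQR(gaps), 4)
  expect_equal(fdBinWidth(gaps), 2.0)
})

test_that("gap-independent densities show no trend across gap bins", {
  # counts drawn independently of the gap (the null of the density-vs-distance
  # analysis): every bin mean must sit within 3 SE of the global mean
  set.seed(21)
  s <- seq(0, 12, 0.05)
  regs <- lapply(1:80, function(i) {
    k <- sample(3:8, 1)
    pos <- 1 + (0:(k - 1)) * (10 / k) + stats::runif(k, -0.3, 0.3)
    y <- 0.1 + Reduce(`+`, lapply(pos, function(m) exp(-(s - m)^2 / (2 * 0.3^2))))
    contactRegion(IntensityProfile(s, y), cellGapUm = stats::runif(1, 1, 25))
  })
  dens <- vapply(regs, contactDensity, numeric(1))
  bs <- densityVsDistance(regs)
  tab <- binTable(bs)
  expect_false(bs@singleBinFallback)
  filled <- tab[tab$n > 1, ]
  se <- stats::sd(dens) / sqrt(filled$n)
  expect_true(all(abs(filled$mean_density - mean(dens)) < 3 * se))
})

test_that("disk perimeter is recovered within 5% of the circle length", {
  r <- 20
  n <- 2 * r + 11
  cc <- (n + 1) / 2
  mask <- outer(1:n, 1:n, function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
  img <- matrix(1, n, n)
  pp <- perimeterProfile(img, mask, pixelSize = 1)
  expect_lt(abs(pp@perimeterUm - 2 * pi * r) / (2 * pi * r), 0.05)
  expect_identical(pp@nFilopodia, 0L)   # uniform intensity on the contour
})

test_that("rendered boundary filopodia set the perimeter density", {
  sc <- simulateContactScene(contactsPerRegion = 0, filopodiaPerCell = 8,
                             noiseSd = 0, seed = 4)
  mask <- sc$truth$cellMasks[[1]]
  pp <- perimeterProfile(sc$image, mask, sc$pixelSize)
  expect_identical(pp@nFilopodia, 8L)
  expect_equal(pp@filopodiaDensity, 8 / pp@perimeterUm)
})

test_that("multi-component or empty masks are rejected", {
  m <- matrix(FALSE, 10, 10); m[2:3, 2:3] <- TRUE; m[7:8, 7:8] <- TRUE
  expect_error(perimeterProfile(matrix(1, 10, 10), m, 1),
               "exactly one connected component")
  expect_error(perimeterProfile(matrix(1, 10, 10),
                                matrix(FALSE, 10, 10), 1), "empty")
})

test_that("group summaries follow the 5-95 percentile whisker convention", {
  gc <- compareGroups(list(a = as.numeric(1:100), b = as.numeric(1:100) + 1))
  expect_equal(gc@summaries$p5, c(5.95, 6.95))
  expect_equal(gc@summaries$p95, c(95.05, 96.05))
  expect_equal(gc@summaries$mean, c(50.5, 51.5))
})

test_that("strongly shifted groups are detected, tiny groups rejected", {
  set.seed(31)
  a <- stats::rnorm(50); b <- stats::rnorm(50, mean = 5)
  gc <- compareGroups(list(control = a, treated = b))
  expect_lt(gc@tests$p_value, 0.001)
  gk <- compareGroups(list(control = a, treated = b), test = "ks")
  expect_lt(gk@tests$p_value, 0.001)
  expect_error(compareGroups(list(a = 1:2, b = 1:5)), "at least 3 values")
})

test_that("null group comparisons are not systematically significant", {
  set.seed(41)
  rej <- mean(replicate(200, {
    compareGroups(list(a = stats::rnorm(20), b = stats::rnorm(20)))@tests$p_value < 0.05
  }))
  expect_lt(rej, 0.12)  # near the nominal 5% level
})
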