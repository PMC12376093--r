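test_that("whittaker solution matches the dense normal-equations oracle", {
  set.seed(11)
  for (n in c(20L, 50L, 200L)) {
    s <- rnorm(n)
    w <- runif(n)
    for (lambda in c(1, 100, 1e5)) {
      z <- whittakerWeighted(s, w, lambda)
      expect_equal(z, as.numeric(denseWhittaker(s, w, lambda)),
                   tolerance = 1e-8)
    }
  }
})

test_that("whittaker limits: vanishing penalty and linear null space", {
  set.seed(12)
  s <- rnorm(60)
  z <- whittakerWeighted(s, rep(1, 60), lambda = 1e-9)
  expect_lt(max(abs(z - s)) / max(abs(s)), 1e-6)
  ## second differences of a line vanish: any lambda reproduces it
  line <- 2 + 0.3 * seq_len(80)
  expect_equal(whittakerWeighted(line, rep(1, 80), 1e8), line,
               tolerance = 1e-7)
  expect_error(whittakerWeighted(s, rep(0, 60), 10),
               class = "tds_degeneracy_error")
  expect_error(whittakerWeighted(s, rep(1, 60), -1),
               class = "tds_parameter_error")
})

test_that("airPLS handles degenerate and peak-free signals", {
  r0 <- airPLS(numeric(50), lambda = 1e5)
  expect_true(r0@converged)
  expect_identical(r0@iterations, 1L)
  expect_equal(r0@baseline, numeric(50))

  ## pure smooth background, no peaks: the baseline is the signal away
  ## from the penalty's boundary layer (width ~ lambda^(1/4) points, where
  ## the natural boundary conditions flatten the curvature)
  x <- seq(0, 1, length.out = 501)
  bg <- 0.3 + 0.4 * x - 0.15 * x^2 + 0.1 * x^3
  r <- airPLS(bg, lambda = 1e5)
  interior <- 60:442
  expect_lt(max(abs(r@baseline - bg)[interior]), 1e-3 * diff(range(bg)))
  expect_lt(max(abs(r@baseline - bg)), 1e-2 * diff(range(bg)))

  expect_error(airPLS(c(1, NA, 3), 1e5), class = "tds_domain_error")
  expect_error(airPLS(bg, lambda = 0), class = "tds_parameter_error")
})

test_that("airPLS recovers a linear ramp under a noisy Gaussian band", {
  ## the estimated baseline rides the lower envelope of the noise, a
  ## constant offset of about -2 noise sd that later cancels in the
  ## calibrant-normalized TDS ratio; the ramp's shape must be recovered
  x <- seq(1500, 1750, by = 0.5)
  ramp <- 0.5 * (x - 1500) / 250
  for (seed in 1:20) {
    set.seed(seed)
    s <- ramp + gaussBand(x, 1625, 1, 16) + rnorm(length(x), sd = 0.01)
    r <- airPLS(s, lambda = 1e5)
    off <- abs(x - 1625) >= 32           # >= 2 FWHM from the band
    dev <- r@baseline[off] - ramp[off]
    expect_lt(max(abs(dev - median(dev))), 0.025)  # shape error (~2.5 sd)
    expect_lt(abs(median(dev)), 3 * 0.01)          # envelope offset
    expect_lt(max(dev), 0.01)                      # stays at/under signal
  }
})

test_that("airPLS is shift-invariant and stays under the signal", {
  set.seed(21)
  x <- seq(0, 1, length.out = 200)
  s <- 0.2 + 0.3 * x + gaussBand(x, 0.5, 1, 0.1) + rnorm(200, sd = 0.05)
  ## a fixed iteration budget pins both runs to the same reweighting path
  ## (the stopping rule itself is relative to |s|, hence not
  ## shift-invariant, and late iterations tie-break on floating-point
  ## signs of ~1e-15 residuals)
  r1 <- airPLS(s, 1e4, maxIter = 6L, terminationRatio = 0)
  r2 <- airPLS(s + 5, 1e4, maxIter = 6L, terminationRatio = 0)
  expect_identical(r1@iterations, r2@iterations)
  expect_equal(r2@baseline, r1@baseline + 5, tolerance = 1e-8)
  ## the baseline exceeds the signal by at most the terminal
  ## negative-residual norm
  expect_lt(max(r1@baseline - s), r1@residualNormRatio * sum(abs(s)) + 1e-9)
})

test_that("airPLS matches a dense reference implementation iterate-for-iterate", {
  set.seed(31)
  for (n in c(50L, 120L, 200L)) {
    x <- seq(0, 1, length.out = n)
    s <- 0.3 + 0.5 * x + gaussBand(x, 0.4, 1, 0.08) + rnorm(n, sd = 0.03)
    ref <- denseAirPLS(s, lambda = 1e4)
    mine <- airPLS(s, lambda = 1e4)
    expect_identical(mine@iterations, length(ref))
    expect_equal(mine@baseline, as.numeric(ref[[length(ref)]]),
                 tolerance = 1e-8)
  }
})

test_that("Savitzky-Golay reproduces polynomials up to its order exactly", {
  x <- seq_len(80)
  for (win in c(5L, 9L, 15L)) {
    cubic <- 1 - 0.2 * x + 0.01 * x^2 - 1e-4 * x^3
    expect_equal(savgolSmooth(cubic, win, 3L), cubic, tolerance = 1e-10)
  }
  expect_equal(savgolSmooth(rep(2.5, 40), 15L, 3L), rep(2.5, 40))
  expect_error(savgolSmooth(rnorm(40), 14L, 3L),
               class = "tds_parameter_error")
  expect_error(savgolSmooth(rnorm(40), 3L, 3L),
               class = "tds_parameter_error")
  expect_error(savgolSmooth(rnorm(10), 15L, 3L), class = "tds_size_error")
})

test_that("Savitzky-Golay equals explicit windowed least squares everywhere", {
  set.seed(41)
  n <- 60
  y <- sin(seq(0, 4 * pi, length.out = n)) + rnorm(n, sd = 0.1)
  sm <- savgolSmooth(y, 15L, 3L)
  h <- 7L
  oracle <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - h):min(n, i + h)      # truncated available window
    fit <- lm(y[idx] ~ poly(idx, 3, raw = TRUE))
    unname(predict(fit, data.frame(idx = i)))
  }, numeric(1))
  expect_equal(sm, oracle, tolerance = 1e-8)
})

test_that("Savitzky-Golay interior agrees with signal::sgolayfilt", {
  skip_if_not_installed("signal")
  set.seed(42)
  y <- cumsum(rnorm(100))
  sm <- savgolSmooth(y, 15L, 3L)
  ref <- signal::sgolayfilt(y, p = 3, n = 15)
  interior <- 8:93
  expect_equal(sm[interior], ref[interior], tolerance = 1e-8)
})

test_that("polynomial baseline recovers matching backgrounds exactly", {
  x <- seq(1500, 1750, by = 0.5)
  bg <- 0.3 - 2e-3 * (x - 1500) + 6e-6 * (x - 1500)^2
  ## narrow band: its wings are < 1e-15 inside the fit windows
  s <- spectrum1d(x, bg + gaussBand(x, 1623, 0.5, 12), role = "od")
  r <- polynomialBaseline(s, 2L, list(c(1550, 1580), c(1670, 1748)))
  expect_lt(max(abs(r@baseline - bg)), 1e-9)
  expect_identical(r@method, "polynomial")

  ## order 0 over one range is the in-range mean
  r0 <- polynomialBaseline(s, 0L, list(c(1700, 1748)))
  inr <- x >= 1700 & x <= 1748
  expect_equal(unique(round(r0@baseline, 12)),
               round(mean((bg + gaussBand(x, 1623, 0.5, 12))[inr]), 12))

  expect_error(polynomialBaseline(s, 2L, list()),
               class = "tds_parameter_error")
  expect_error(polynomialBaseline(s, 5L, list(c(1550, 1551))),
               class = "tds_degeneracy_error")
})

test_that("polynomial baseline equals a direct normal-equations solve", {
  set.seed(51)
  x <- seq(1500, 1750, by = 0.5)
  bg <- 0.2 + 1e-3 * (x - 1500) - 5e-6 * (x - 1500)^2 + 2e-8 * (x - 1500)^3
  y <- bg + gaussBand(x, 1620, 0.4, 20) + rnorm(length(x), sd = 0.005)
  s <- spectrum1d(x, y, role = "od")
  ranges <- list(c(1550, 1570), c(1705, 1748))
  r <- polynomialBaseline(s, 3L, ranges)
  sel <- (x >= 1550 & x <= 1570) | (x >= 1705 & x <= 1748)
  fit <- lm(y[sel] ~ poly(x[sel], 3, raw = TRUE))
  oracle <- as.numeric(cbind(1, x, x^2, x^3) %*% coef(fit))
  expect_equal(r@baseline, oracle, tolerance = 1e-6)
})

test_that("correctBaseline returns corrected spectra with provenance", {
  x <- seq(1500, 1750, by = 0.5)
  z <- spectrum1d(x, numeric(length(x)) , role = "od")
  cb <- correctBaseline(z, "airpls")
  expect_equal(specValues(cb$corrected), numeric(length(x)))
  expect_identical(specMeta(cb$corrected)$baseline_method, "airpls")
  expect_error(correctBaseline(z, "polynomial"),
               class = "tds_parameter_error")
})

test_that("band apex survives airPLS correction within a few percent", {
  ## weakest rung of the concentration ladder; includes smoothing as used
  ## for low signal-to-noise data
  errs <- vapply(1:20, function(seed) {
    ds <- synthDataset(serineConfig(amplitudeScale = 0.25, seed = seed))
    cb <- correctBaseline(ds$od, "airpls", lambda = 1e6, presmooth = TRUE)
    x <- waveAxis(ds$od)
    apex <- max(specValues(cb$corrected)[abs(x - 1623) < 5])
    abs(apex - 0.25 * 0.200) / (0.25 * 0.200)
  }, numeric(1))
  expect_lt(mean(errs), 0.03)
  ## corrected OD stays positive at the apex in every seed
  expect_true(all(errs < 0.1))
})

test_that("the manual polynomial pathway also recovers the apex on clean data", {
  ds <- synthDataset(serineConfig(amplitudeScale = 1, noiseSdOD = 0))
  cb <- correctBaseline(ds$od, "polynomial", order = 2L,
                        fitRanges = list(c(1550, 1590), c(1660, 1748)))
  x <- waveAxis(ds$od)
  apex <- max(specValues(cb$corrected)[abs(x - 1623) < 5])
  expect_lt(abs(apex - 0.2) / 0.2, 0.05)
})
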