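test_that("1D reader parses, sorts on read, and records the role", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "1600, 0.1", "1610\t0.2", "1620 0.3"), p)
  s <- readSpectrum1D(p, role = "od")
  expect_s4_class(s, "Spectrum1D")
  expect_equal(waveAxis(s), c(1600, 1610, 1620))
  expect_equal(specValues(s), c(0.1, 0.2, 0.3))
  expect_identical(specRole(s), "od")

  writeLines(c("1620 0.3", "1600 0.1", "1610 0.2"), p)
  expect_equal(specValues(readSpectrum1D(p)), c(0.1, 0.2, 0.3))
})

test_that("1D reader rejects malformed input with line numbers", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1600 0.1", "1610 oops", "1620 0.3"), p)
  expect_error(readSpectrum1D(p), "line 2", class = "tds_parse_error")
  writeLines(c("1600 0.1", "1610 0.2 0.5"), p)
  expect_error(readSpectrum1D(p), "line 2", class = "tds_parse_error")
  writeLines(c("1600 0.1", "1610 0.2"), p)
  expect_error(readSpectrum1D(p), class = "tds_size_error")
  writeLines(c("1600 0.1", "1610 0.2", "1610 0.3"), p)
  expect_error(readSpectrum1D(p), class = "tds_duplicate_axis_error")
  expect_error(readSpectrum1D(file.path(tempdir(), "nope.tsv")),
               class = "tds_io_error")
})

test_that("1D write/read round-trips values and masks", {
  p <- withr::local_tempfile(fileext = ".tsv")
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    s <- randomSpectrum(n = sample(5:60, 1), masked = sample(0:2, 1))
    writeSpectrum1D(s, p)
    r <- readSpectrum1D(p, role = specRole(s))
    expect_identical(validMask(r), validMask(s))
    ok <- validMask(s)
    relerr <- max(abs(specValues(r)[ok] - specValues(s)[ok]) /
                    pmax(abs(specValues(s)[ok]), 1e-300))
    worst <- max(worst, relerr,
                 max(abs(waveAxis(r) - waveAxis(s)) / waveAxis(s)))
  }
  expect_lt(worst, 1e-9)
})

test_that("masked points are written as empty-value rows", {
  p <- withr::local_tempfile(fileext = ".tsv")
  s <- spectrum1d(c(1600, 1610, 1620), c(0.1, NA, 0.3), role = "tds",
                  mask = c(TRUE, FALSE, TRUE))
  writeSpectrum1D(s, p)
  rows <- grep("^[^#]", readLines(p), value = TRUE)
  expect_length(rows, 3L)
  expect_match(rows[2L], "^1610\\t$")
})

test_that("2D reader handles headers, sorting, and bad cells", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("pump\\probe 1600 1610", "1605 1 2", "1595 3 4"), p)
  s <- readSpectrum2D(p)
  expect_equal(pumpAxis(s), c(1595, 1605))
  expect_equal(signalMatrix(s), matrix(c(3, 1, 4, 2), 2, 2))

  writeLines(c("pump\\probe 1600 1610", "1595 1 2", "1605 1 2 3"), p)
  expect_error(readSpectrum2D(p), "ragged", class = "tds_parse_error")
  writeLines(c("pump\\probe 1600 1610", "1595 1 x", "1605 2 3"), p)
  expect_error(readSpectrum2D(p), "line 2, field 3",
               class = "tds_parse_error")
})

test_that("a generated 64x64 spectrum round-trips through write/read", {
  cfg <- synthConfig(axis = c(1560, 1686, 2), noiseSd2D = 1e-5)
  ds <- synthDataset(cfg, include2D = TRUE)
  expect_length(pumpAxis(ds$spec2d), 64L)
  p <- withr::local_tempfile(fileext = ".txt")
  writeSpectrum2D(ds$spec2d, p)
  r <- readSpectrum2D(p)
  expect_equal(pumpAxis(r), pumpAxis(ds$spec2d), tolerance = 1e-9)
  expect_equal(signalMatrix(r), signalMatrix(ds$spec2d), tolerance = 1e-9)
})

test_that("diagonal extraction is exact on grid nodes", {
  ax <- seq(1500, 1600, by = 10)
  set.seed(5)
  M <- matrix(abs(rnorm(121)) + 0.1, 11, 11)
  s <- spectrum2d(ax, ax, M)
  d <- extractDiagonal(s, ax)
  expect_equal(specValues(d), diag(M), tolerance = 1e-12)

  ## separable surface: diagonal = f * g at the nodes
  f <- 1 + sin(ax / 30)^2; g <- 2 + cos(ax / 40)
  d2 <- extractDiagonal(spectrum2d(ax, ax, outer(f, g)), ax)
  expect_equal(specValues(d2), f * g, tolerance = 1e-12)

  ## constant matrix
  d3 <- extractDiagonal(spectrum2d(ax, ax, matrix(3, 11, 11)), ax)
  expect_equal(specValues(d3), rep(3, 11))
})

test_that("off-grid diagonal values respect the bilinear error bound", {
  ax <- seq(1600, 1650, by = 0.5)
  sd2 <- 8
  surf <- function(p, q) exp(-((p - 1623)^2 + (q - 1623)^2) / (2 * sd2^2))
  M <- outer(ax, ax, surf)
  out <- seq(1605.13, 1645.13, by = 1)   # deliberately off-grid
  d <- extractDiagonal(spectrum2d(ax, ax, M), out)
  truth <- surf(out, out)
  ## bilinear error <= h^2/8 * max second derivative per axis (x2 axes)
  bound <- 2 * (0.5^2 / 8) * (1 / sd2^2)
  expect_lt(max(abs(specValues(d) - truth)), bound)
})

test_that("diagonal extraction handles signs and range errors", {
  ax <- seq(1600, 1650, by = 1)
  M <- -outer(gaussBand(ax, 1623, 1, 10), gaussBand(ax, 1623, 1, 10))
  d <- extractDiagonal(spectrum2d(ax, ax, M), ax)   # bleach convention
  expect_true(all(specValues(d) >= 0))

  Mmix <- M; Mmix[1:10, ] <- -M[1:10, ] + 0.5
  expect_error(extractDiagonal(spectrum2d(ax, ax, Mmix), ax),
               class = "tds_data_error")
  expect_error(extractDiagonal(spectrum2d(ax, ax, M), c(1590, 1620, 1630)),
               class = "tds_range_error")
})

test_that("transmission -> OD inverts and matches the pointwise oracle", {
  ax <- seq(1500, 1600, length.out = 50)
  set.seed(7)
  ref <- spectrum1d(ax, runif(50, 0.5, 2))
  smp <- spectrum1d(ax, specValues(ref) * 10^(-runif(50, 0, 1.5)))
  od <- transmissionToOD(smp, ref)
  expect_equal(specValues(od),
               -log10(specValues(smp) / specValues(ref)), tolerance = 1e-12)
  ## identity and closed form
  expect_equal(specValues(transmissionToOD(ref, ref)), rep(0, 50))
  tenth <- spectrum1d(ax, specValues(ref) / 10)
  expect_equal(specValues(transmissionToOD(tenth, ref)), rep(1, 50))
  ## inverse round-trip
  back <- specValues(ref) * 10^(-specValues(od))
  expect_equal(back, specValues(smp), tolerance = 1e-12)
  neg <- spectrum1d(ax, replace(specValues(ref), 3, -1))
  expect_error(transmissionToOD(neg, ref), class = "tds_domain_error")
})

test_that("resampling is identity on the native axis and exact on ramps", {
  s <- randomSpectrum(n = 30, seed = 9)
  expect_equal(specValues(resampleToAxis(s, waveAxis(s))), specValues(s),
               tolerance = 1e-12)
  ax <- seq(1500, 1700, by = 2)
  ramp <- spectrum1d(ax, 3 + 0.01 * ax)
  tgt <- seq(1501.3, 1698.7, by = 3.1)
  expect_equal(specValues(resampleToAxis(ramp, tgt)), 3 + 0.01 * tgt,
               tolerance = 1e-12)
  expect_error(resampleToAxis(ramp, c(1499, 1500, 1600)),
               class = "tds_range_error")
})

test_that("linear resampling of a dense Gaussian obeys the curvature bound", {
  ax <- seq(1580, 1660, by = 0.25)
  sdg <- 6
  g <- spectrum1d(ax, exp(-(ax - 1620)^2 / (2 * sdg^2)))
  tgt <- seq(1580, 1660, by = 0.5)[-1]
  r <- resampleToAxis(g, tgt)
  bound <- (0.25^2 / 8) * (1 / sdg^2)   # h^2/8 * max|f''|
  expect_lt(max(abs(specValues(r) - exp(-(tgt - 1620)^2 / (2 * sdg^2)))),
            bound)
})

test_that("solvent subtraction removes a known background exactly", {
  ax <- seq(1500, 1700, by = 1)
  band <- gaussBand(ax, 1623, 0.2, 18)
  solvent <- spectrum1d(ax, 0.05 + 1e-4 * (ax - 1500), role = "od")
  sample <- spectrum1d(ax, band + 0.7 * specValues(solvent), role = "od")
  res <- subtractSolvent(sample, solvent, scale = 0.7)
  expect_equal(specValues(res), band, tolerance = 1e-12)
  expect_true(isTRUE(specMeta(res)$solvent_subtracted))
  ## scale 0 leaves the sample unchanged; equal spectra cancel
  expect_equal(specValues(subtractSolvent(sample, solvent, 0)),
               specValues(sample))
  expect_equal(specValues(subtractSolvent(solvent, solvent, 1)),
               rep(0, length(ax)))
})

test_that("masks propagate through resampling and arithmetic", {
  ax <- seq(1500, 1590, by = 10)
  v <- seq_len(10)
  s <- spectrum1d(ax, replace(v, 4, NA), mask = replace(rep(TRUE, 10), 4, FALSE))
  ## 1531 interpolates from the masked 1530 point; 1545 does not
  r <- resampleToAxis(s, c(1512, 1531, 1545, 1571))
  expect_identical(validMask(r), c(TRUE, FALSE, TRUE, TRUE))
  other <- spectrum1d(waveAxis(r), rep(1, 4))
  expect_identical(validMask(subtractSolvent(other, r)), validMask(r))
})
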