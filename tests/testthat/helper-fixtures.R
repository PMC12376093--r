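# fixtures are built in code; nothing is stored on disk

randomSpectrum <- function(n = 40, seed = NULL, role = "generic",
                           masked = 0L) {
  if (!is.null(seed)) set.seed(seed)
  axis <- sort(1000 + runif(n, 0, 800))
  while (anyDuplicated(axis)) axis <- sort(1000 + runif(n, 0, 800))
  vals <- rnorm(n)
  mask <- rep(TRUE, n)
  if (masked > 0L) {
    off <- sample(n, masked)
    mask[off] <- FALSE
    vals[off] <- NA_real_
  }
  spectrum1d(axis, vals, role = role, mask = mask)
}

## dense-matrix oracle for the weighted Whittaker normal equations
denseWhittaker <- function(s, w, lambda, d = 2L) {
  n <- length(s)
  D <- diff(diag(n), differences = d)
  solve(diag(w, n) + lambda * t(D) %*% D, w * s)
}

## independent airPLS reference: same published weight scheme, dense solves
denseAirPLS <- function(s, lambda, maxIter = 15L, term = 0.001) {
  n <- length(s)
  w <- rep(1, n)
  absS <- sum(abs(s))
  zs <- list()
  for (t in seq_len(maxIter)) {
    z <- denseWhittaker(s, w, lambda)
    zs[[t]] <- z
    d <- s - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (dssn / absS < term) break
    w <- numeric(n)
    w[neg] <- exp(t * abs(d[neg]) / dssn)
  }
  zs
}

gaussBand <- function(x, center, height, fwhm) {
  height * exp(-4 * log(2) * ((x - center) / fwhm)^2)
}

## the l-serine emulation used throughout validation: Gaussian carboxyl-like
## band, mu2 = 0.200 D^2, quadratic background, broadband Gaussian pump;
## amplitudeScale 1 ~ the 40 mM sample (apex OD 0.2)
serineConfig <- function(amplitudeScale = 1, seed = 1L, noiseSdOD = 1.5e-3,
                         ...) {
  synthConfig(
    bands = list(bandSpec(1623, 16, 0.200, shape = "gaussian",
                          amplitudeScale = amplitudeScale)),
    calibrant = bandSpec(1623, 16, 0.200, shape = "gaussian"),
    noiseSdOD = noiseSdOD, seed = seed, ...)
}

serineCalibrant <- function(ds)
  calibrantFromSpectra(ds$calibrantDiag, ds$calibrantOD,
                       mu2 = ds$config$calibrant$mu2, name = "synthetic")

## run baseline correction + TDS assembly the way the validation study does
runSerinePipeline <- function(ds, lambda = 1e6, presmooth = TRUE,
                              normalizePump = TRUE) {
  cb <- correctBaseline(ds$od, method = "airpls", lambda = lambda,
                        presmooth = presmooth)
  computeTDS(ds$diag, cb$corrected, serineCalibrant(ds), pump = ds$pump,
             normalizePump = normalizePump)
}
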