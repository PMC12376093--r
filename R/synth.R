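## Synthetic-data generator.
##
## Forward model, chosen so the TDS equation inverts it exactly:
##   band-wise linear-OD contribution  A_k(w) = c_k * mu2_k * g_k(w)
##   OD(w)        = sum_k A_k(w) + polynomial background + N(0, sd_od)
##   dOD(w, w)    = kappa * I_pump(w) * sum_k mu2_k * A_k(w) + N(0, sd_2d)
## with g_k a unit-maximum lineshape. For an isolated band the noiseless
## ratio dOD/OD at any w inside the band is kappa * I_pump(w) * mu2_k, so
## scaling by a calibrant generated from the same model and normalizing the
## pump returns mu2_k exactly -- OD scales as mu^2 and the 2D diagonal as
## mu^4, as in the experiment. Concentration enters only through c_k and
## cancels in the ratio.

.lineshape <- function(x, center, fwhm, shape, eta) {
  u <- x - center
  g <- exp(-4 * log(2) * (u / fwhm)^2)
  l <- 1 / (1 + (2 * u / fwhm)^2)
  switch(shape,
    gaussian = g,
    lorentzian = l,
    pseudo_voigt = eta * l + (1 - eta) * g,
    tdsStop("tds_parameter_error", sprintf("unknown lineshape '%s'", shape)))
}

#' Describe a synthetic absorption band
#'
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param mu2 ground-truth transition dipole strength (D^2), >= 0.
#' @param shape \code{"pseudo_voigt"} (default), \code{"gaussian"} or
#'   \code{"lorentzian"}.
#' @param eta pseudo-Voigt Lorentzian fraction in [0, 1] (default 0.5).
#' @param amplitudeScale concentration-like factor c; with unit-maximum
#'   lineshapes the band's apex OD is \code{amplitudeScale * mu2}.
#' @return a \code{band_spec} list.
#' @seealso [synthConfig()]
#' @export
bandSpec <- function(center, fwhm, mu2, shape = "pseudo_voigt", eta = 0.5,
                     amplitudeScale = 1.0) {
  if (fwhm <= 0) tdsStop("tds_parameter_error", "fwhm must be positive")
  if (mu2 < 0) tdsStop("tds_parameter_error", "mu2 must be nonnegative")
  if (eta < 0 || eta > 1)
    tdsStop("tds_parameter_error", "eta must lie in [0, 1]")
  structure(list(center = center, fwhm = fwhm, mu2 = mu2, shape = shape,
                 eta = eta, amplitudeScale = amplitudeScale),
            class = "band_spec")
}

#' Configure the synthetic-spectrum generator
#'
#' Defaults emulate the l-serine validation scenario: a single
#' carboxyl-stretch-like band at 1623 cm^-1 with the established dipole
#' strength 0.200 D^2, on a smooth quadratic background over the
#' 1500-1750 cm^-1 amide I' window, probed with a broadband Gaussian pump
#' envelope. \code{amplitudeScale = 1} corresponds to the strongest
#' (40 mM-like) sample with an apex OD of 0.2; scale it down for the
#' weaker-concentration emulations. Noise is additive white Gaussian on
#' both the OD and the 2D diagonal, with defaults reflecting
#' instrument-limited absorbance noise after signal averaging (the large,
#' sloped background -- the component baseline correction must remove -- is
#' carried by the polynomial, not the noise term).
#'
#' @param bands list of [bandSpec()] entries.
#' @param baselineCoeffs polynomial background coefficients (ascending
#'   powers) in the normalized coordinate \eqn{u = (\omega - lo)/(hi - lo)}.
#' @param noiseSdOD white-noise sd on the linear OD (OD units).
#' @param noiseSd2D white-noise sd on the 2D diagonal (delta-OD units).
#' @param pump \code{list(type = "gaussian", center, fwhm)} or
#'   \code{list(type = "flat")}.
#' @param axis \code{c(lo, hi, step)} in cm^-1.
#' @param kappa instrument scaling constant linking OD to the 2D diagonal
#'   (arbitrary units, > 0).
#' @param calibrant [bandSpec()] for the (always noiseless, baseline-free)
#'   calibrant band.
#' @param seed integer RNG seed.
#' @return a \code{synth_config} list.
#' @export
synthConfig <- function(bands = list(bandSpec(1623, 16, 0.200)),
                        baselineCoeffs = c(0.20, -0.15, 0.10),
                        noiseSdOD = 1.5e-3,
                        noiseSd2D = 1e-5,
                        pump = list(type = "gaussian", center = 1620,
                                    fwhm = 120),
                        axis = c(1500, 1750, 0.5),
                        kappa = 1.0,
                        calibrant = bandSpec(1623, 16, 0.200),
                        seed = 1L) {
  if (axis[3L] <= 0) tdsStop("tds_parameter_error", "axis step must be > 0")
  if (kappa <= 0) tdsStop("tds_parameter_error", "kappa must be > 0")
  if (noiseSdOD < 0 || noiseSd2D < 0)
    tdsStop("tds_parameter_error", "noise sds must be nonnegative")
  structure(list(bands = bands, baselineCoeffs = baselineCoeffs,
                 noiseSdOD = noiseSdOD, noiseSd2D = noiseSd2D, pump = pump,
                 axis = axis, kappa = kappa, calibrant = calibrant,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.synthAxis <- function(config) {
  seq(config$axis[1L], config$axis[2L], by = config$axis[3L])
}

.pumpValues <- function(config, x) {
  p <- config$pump
  if (identical(p$type, "flat")) rep(1.0, length(x))
  else if (identical(p$type, "gaussian"))
    exp(-4 * log(2) * ((x - p$center) / p$fwhm)^2)
  else tdsStop("tds_parameter_error",
               sprintf("unknown pump type '%s'", p$type))
}

.bandOD <- function(band, x) {
  band$amplitudeScale * band$mu2 *
    .lineshape(x, band$center, band$fwhm, band$shape, band$eta)
}

.warnOverlaps <- function(bands) {
  if (length(bands) < 2L) return(invisible(NULL))
  for (i in seq_len(length(bands) - 1L)) for (j in (i + 1L):length(bands)) {
    sep <- abs(bands[[i]]$center - bands[[j]]$center)
    if (sep < 0.5 * max(bands[[i]]$fwhm, bands[[j]]$fwhm))
      tdsWarn("tds_overlap_warning",
              sprintf("bands at %g and %g cm-1 overlap (separation %.3g < FWHM/2): ground truth at the maxima becomes a mu^2-weighted mixture",
                      bands[[i]]$center, bands[[j]]$center, sep))
  }
  invisible(NULL)
}

## noiseless components shared by the static and kinetics generators
.synthClean <- function(config, x) {
  A <- vapply(config$bands, .bandOD, numeric(length(x)), x = x)
  A <- if (is.matrix(A)) A else matrix(A, ncol = length(config$bands))
  mu2 <- vapply(config$bands, `[[`, numeric(1), "mu2")
  u <- (x - config$axis[1L]) / (config$axis[2L] - config$axis[1L])
  bg <- as.numeric(outer(u, seq_along(config$baselineCoeffs) - 1L, `^`) %*%
                     config$baselineCoeffs)
  pump <- .pumpValues(config, x)
  list(odClean = rowSums(A) + bg,
       diagClean = config$kappa * pump * as.numeric(A %*% mu2),
       pump = pump, bandOD = A)
}

#' Generate a mutually consistent synthetic dataset
#'
#' Produces linear OD, 2D diagonal, pump, and noiseless calibrant spectra
#' from the same forward model, so that running the full baseline +
#' TDS pipeline against the generated calibrant recovers each band's
#' ground-truth \eqn{\mu^2} (exactly, in the zero-noise zero-background
#' limit). Deterministic given the config seed (Mersenne-Twister).
#'
#' @param config a [synthConfig()].
#' @param include2D also build the full pump x probe [Spectrum2D-class]
#'   surface whose diagonal matches the 1D diagonal (default \code{FALSE}).
#' @return list with [Spectrum1D-class] elements \code{od}, \code{diag},
#'   \code{pump}, \code{calibrantOD}, \code{calibrantDiag}; optionally
#'   \code{spec2d}; \code{truth} (data.frame of band centers and
#'   \eqn{\mu^2}); and the \code{config}.
#' @examples
#' ds <- synthDataset(synthConfig(noiseSdOD = 0, baselineCoeffs = 0))
#' ds$truth
#' @export
synthDataset <- function(config, include2D = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  .warnOverlaps(config$bands)
  x <- .synthAxis(config)
  set.seed(config$seed)
  cl <- .synthClean(config, x)
  od <- cl$odClean + rnorm(length(x), sd = config$noiseSdOD)
  dg <- abs(cl$diagClean + rnorm(length(x), sd = config$noiseSd2D))
  calOD <- .bandOD(config$calibrant, x)
  calDiag <- config$kappa * cl$pump * config$calibrant$mu2 * calOD
  out <- list(
    od = spectrum1d(x, od, role = "od", meta = list(synthetic = TRUE)),
    diag = spectrum1d(x, dg, role = "delta_od_diag",
                      meta = list(synthetic = TRUE)),
    pump = spectrum1d(x, cl$pump, role = "pump",
                      meta = list(synthetic = TRUE)),
    calibrantOD = spectrum1d(x, calOD, role = "od",
                             meta = list(synthetic = TRUE)),
    calibrantDiag = spectrum1d(x, calDiag, role = "delta_od_diag",
                               meta = list(synthetic = TRUE)),
    truth = data.frame(
      center = vapply(config$bands, `[[`, numeric(1), "center"),
      mu2 = vapply(config$bands, `[[`, numeric(1), "mu2")),
    config = config)
  if (include2D) {
    mu2 <- vapply(config$bands, `[[`, numeric(1), "mu2")
    H <- sqrt(pmax(cl$bandOD, 0))         # h_k(w) with h_k^2 = A_k
    S <- matrix(0, length(x), length(x))
    for (k in seq_along(config$bands))
      S <- S + mu2[k] * tcrossprod(H[, k])
    S <- config$kappa * cl$pump * S       # rows scaled by I_pump(pump axis)
    out$spec2d <- spectrum2d(x, x, S, meta = list(synthetic = TRUE))
  }
  out
}

#' Generate a synthetic aggregation-kinetics series
#'
#' Frame-wise application of the static forward model with time-varying
#' band dipole strengths (and optionally amplitudes), emulating continuous
#' 2D IR acquisition during amyloid aggregation: one diagonal slice and one
#' linear OD per frame, with independent seeded noise per frame.
#'
#' @param config a [synthConfig()]; per-frame noise uses its noise sds.
#' @param nFrames number of frames.
#' @param cadenceS seconds per frame (default 66, one 2D IR spectrum per
#'   acquisition block).
#' @param mu2Trajectories list (one per band) of functions of time
#'   (seconds) returning \eqn{\mu^2(t)}; \code{NULL} entries keep the
#'   config value constant.
#' @param amplitudeTrajectories like \code{mu2Trajectories} for the
#'   concentration-like amplitude scale.
#' @param startTime time of the first frame (seconds, default 0; use this
#'   for the dead time between initiating aggregation and the first
#'   spectrum).
#' @return list with \code{diagSeries} and \code{odSeries}
#'   ([SpectrumSeries-class]), \code{pump}, \code{calibrantOD},
#'   \code{calibrantDiag} ([Spectrum1D-class]), and \code{truth}
#'   (list with \code{times} and the \code{mu2} matrix, frames x bands).
#' @export
synthKinetics <- function(config, nFrames, cadenceS = 66,
                          mu2Trajectories = NULL,
                          amplitudeTrajectories = NULL, startTime = 0) {
  stopifnot(inherits(config, "synth_config"))
  if (nFrames < 1L) tdsStop("tds_size_error", "nFrames must be >= 1")
  x <- .synthAxis(config)
  ## frame timestamps are acquisition-period midpoints
  times <- startTime + (seq_len(nFrames) - 0.5) * cadenceS
  nb <- length(config$bands)
  set.seed(config$seed)
  mu2Truth <- matrix(NA_real_, nFrames, nb)
  odFrames <- vector("list", nFrames)
  dgFrames <- vector("list", nFrames)
  pump <- .pumpValues(config, x)
  for (f in seq_len(nFrames)) {
    cfgF <- config
    for (k in seq_len(nb)) {
      if (!is.null(mu2Trajectories) && !is.null(mu2Trajectories[[k]]))
        cfgF$bands[[k]]$mu2 <- mu2Trajectories[[k]](times[f])
      if (!is.null(amplitudeTrajectories) &&
          !is.null(amplitudeTrajectories[[k]]))
        cfgF$bands[[k]]$amplitudeScale <-
          amplitudeTrajectories[[k]](times[f])
      mu2Truth[f, k] <- cfgF$bands[[k]]$mu2
    }
    cl <- .synthClean(cfgF, x)
    odFrames[[f]] <- spectrum1d(
      x, cl$odClean + rnorm(length(x), sd = config$noiseSdOD), role = "od")
    dgFrames[[f]] <- spectrum1d(
      x, abs(cl$diagClean + rnorm(length(x), sd = config$noiseSd2D)),
      role = "delta_od_diag")
  }
  calOD <- .bandOD(config$calibrant, x)
  calDiag <- config$kappa * pump * config$calibrant$mu2 * calOD
  list(diagSeries = spectrumSeries(times, dgFrames, cadence = cadenceS,
                                   meta = list(startOffset = startTime)),
       odSeries = spectrumSeries(times, odFrames, cadence = cadenceS,
                                 meta = list(startOffset = startTime)),
       pump = spectrum1d(x, pump, role = "pump"),
       calibrantOD = spectrum1d(x, calOD, role = "od"),
       calibrantDiag = spectrum1d(x, calDiag, role = "delta_od_diag"),
       truth = list(times = times, mu2 = mu2Truth))
}
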