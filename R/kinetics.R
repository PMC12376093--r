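#' Construct a SpectrumSeries
#'
#' @param times seconds since the start of the experiment, strictly
#'   increasing, one per frame; by convention the timestamp is the middle of
#'   the frame's acquisition period.
#' @param frames list of [Spectrum1D-class] (diagonal slices) or
#'   [Spectrum2D-class] on a common axis.
#' @param cadence nominal seconds per frame (default: median time step).
#' @param meta named list.
#' @return a [SpectrumSeries-class].
#' @export
spectrumSeries <- function(times, frames, cadence = NULL, meta = list()) {
  if (!length(frames)) tdsStop("tds_size_error", "series has no frames")
  if (is.null(cadence))
    cadence <- if (length(times) > 1L) median(diff(times)) else NA_real_
  new("SpectrumSeries", times = as.numeric(times), frames = frames,
      cadence = cadence, meta = meta)
}

#' Block-average a spectrum series
#'
#' Pointwise mean of consecutive frames in windows of \code{windowFrames}
#' frames advancing by \code{stride}, to trade time resolution for
#' signal-to-noise (the noise sd of each averaged frame drops by
#' \eqn{\sqrt{windowFrames}}). The default non-overlapping stride
#' partitions the series into blocks, the usage for aggregation kinetics
#' (e.g. 15 spectra at 66 s cadence per ~16.5 min window); a smaller
#' stride gives overlapping windows and smoother traces. Each output time
#' is the midpoint of its window's time span: with frame timestamps at
#' frame centers, a 15-frame window at 66 s cadence spans 990 s and its
#' output time falls 495 s after the window's start. A trailing partial
#' window is dropped. The spanned duration
#' (\code{windowFrames * cadence}) is recorded as \code{windowSpan} in the
#' output metadata.
#'
#' @param series a [SpectrumSeries-class] of [Spectrum1D-class] frames.
#' @param windowFrames frames per window (default 15), <= frame count.
#' @param stride frames advanced between windows (default
#'   \code{windowFrames}).
#' @return a [SpectrumSeries-class] of averaged frames.
#' @export
windowAverage <- function(series, windowFrames = 15L, stride = windowFrames) {
  nf <- length(series@frames)
  windowFrames <- as.integer(windowFrames); stride <- as.integer(stride)
  if (nf == 0L) tdsStop("tds_size_error", "empty series")
  if (windowFrames < 1L || windowFrames > nf)
    tdsStop("tds_size_error",
            sprintf("windowFrames (%d) must be in 1..%d", windowFrames, nf))
  if (stride < 1L) tdsStop("tds_parameter_error", "stride must be >= 1")
  if (!is(series@frames[[1L]], "Spectrum1D"))
    tdsStop("tds_parameter_error",
            "windowAverage expects Spectrum1D frames (extract diagonals first)")
  starts <- seq(1L, nf - windowFrames + 1L, by = stride)
  cad <- if (is.finite(series@cadence)) series@cadence else 0
  outFrames <- vector("list", length(starts))
  outTimes <- numeric(length(starts))
  ax <- series@frames[[1L]]@axis
  for (w in seq_along(starts)) {
    i <- starts[w]:(starts[w] + windowFrames - 1L)
    V <- vapply(series@frames[i], function(f) f@values, numeric(length(ax)))
    M <- vapply(series@frames[i], function(f) f@mask, logical(length(ax)))
    mask <- apply(M, 1L, all)
    vals <- rowMeans(V)
    vals[!mask] <- NA_real_
    outFrames[[w]] <- spectrum1d(ax, vals, role = series@frames[[i[1L]]]@role,
                                 mask = mask)
    outTimes[w] <- (series@times[i[1L]] + series@times[i[windowFrames]]) / 2
  }
  spectrumSeries(outTimes, outFrames, cadence = stride * cad,
                 meta = c(series@meta,
                          list(windowFrames = windowFrames, stride = stride,
                               windowSpan = windowFrames * cad)))
}

#' Per-frame diagonal intensity at a probe frequency
#'
#' The magnitude of the diagonal \eqn{\Delta}OD at one frequency for every
#' frame of the series -- the conventional fibril-growth readout (e.g. the
#' beta-sheet amide I' mode at 1623 cm^-1), analogous to a thioflavin-T
#' kinetic trace.
#'
#' @param series a [SpectrumSeries-class] ([Spectrum1D-class] diagonals or
#'   [Spectrum2D-class] frames).
#' @param frequency probe wavenumber (cm^-1), inside the frame axis.
#' @return a [KineticsTrace-class] (kind \code{"intensity"}).
#' @export
intensityTrace <- function(series, frequency) {
  f1 <- series@frames[[1L]]
  vals <- if (is(f1, "Spectrum1D")) {
    rng <- range(f1@axis)
    if (frequency < rng[1L] || frequency > rng[2L])
      tdsStop("tds_range_error", "frequency outside the frame axis")
    vapply(series@frames, function(f)
      abs(approx(f@axis, f@values, frequency)$y), numeric(1))
  } else {
    if (frequency < min(f1@pumpAxis) || frequency > max(f1@pumpAxis) ||
        frequency < min(f1@probeAxis) || frequency > max(f1@probeAxis))
      tdsStop("tds_range_error", "frequency outside the pump or probe axis")
    vapply(series@frames, function(f)
      abs(.bilinear(f@pumpAxis, f@probeAxis, f@signal, frequency,
                    frequency)), numeric(1))
  }
  new("KineticsTrace", times = series@times, values = vals,
      kind = "intensity", frequency = frequency, meta = list())
}

#' TDS kinetics trace at a probe frequency
#'
#' Runs the full TDS pipeline per averaged window: block-average the
#' diagonal and linear-OD series identically, baseline-correct each
#' window's OD (Savitzky-Golay presmoothing then airPLS), assemble the TDS
#' spectrum against the calibrant, and read the value at \code{frequency}
#' (nearest axis point by default). Windows whose readout is masked by the
#' OD floor guard yield \code{NA} in the trace -- they are reported, not
#' dropped.
#'
#' @param series diagonal [SpectrumSeries-class] (role
#'   \code{"delta_od_diag"} frames).
#' @param odSeries matching linear-OD [SpectrumSeries-class] (same frame
#'   times).
#' @param frequency readout wavenumber (cm^-1).
#' @param calibrant a [CalibrantReference-class] (evaluated once for the
#'   whole experiment).
#' @param pump optional pump [Spectrum1D-class].
#' @param normalizePump apply pump normalization (default \code{FALSE}).
#' @param windowFrames,stride see [windowAverage()].
#' @param lambda,presmooth,sgWindow,sgOrder baseline parameters (see
#'   [correctBaseline()]).
#' @param odFloorFraction OD guard (see [ratioSpectrum()]).
#' @param mode readout mode for [tdsAt()] (default \code{"nearest"}).
#' @return a [KineticsTrace-class] (kind \code{"tds"}, values in D^2).
#' @export
tdsTrace <- function(series, odSeries, frequency, calibrant, pump = NULL,
                     normalizePump = FALSE, windowFrames = 15L,
                     stride = windowFrames, lambda = 1e5, presmooth = TRUE,
                     sgWindow = 15L, sgOrder = 3L, odFloorFraction = 0.01,
                     mode = "nearest") {
  if (length(series@frames) != length(odSeries@frames))
    tdsStop("tds_size_error",
            "diagonal and OD series must have the same frame count")
  wDiag <- windowAverage(series, windowFrames, stride)
  wOD <- windowAverage(odSeries, windowFrames, stride)
  vals <- vapply(seq_along(wDiag@frames), function(w) {
    cb <- correctBaseline(wOD@frames[[w]], method = "airpls",
                          lambda = lambda, presmooth = presmooth,
                          sgWindow = sgWindow, sgOrder = sgOrder)
    tds <- computeTDS(wDiag@frames[[w]], cb$corrected, calibrant,
                      pump = pump, normalizePump = normalizePump,
                      odFloorFraction = odFloorFraction)
    tryCatch(tdsAt(tds, frequency, mode = mode)@value,
             tds_masked_error = function(e) NA_real_)
  }, numeric(1))
  new("KineticsTrace", times = wDiag@times, values = vals, kind = "tds",
      frequency = frequency,
      meta = list(windowFrames = windowFrames, stride = stride,
                  lambda = lambda, presmooth = presmooth,
                  normalizePump = normalizePump,
                  calibrant = calibrant@name))
}
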