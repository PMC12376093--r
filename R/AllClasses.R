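#' @import methods
#' @importFrom stats approx lm lm.fit median qt sd setNames rnorm coef predict
#' @importFrom utils head tail packageVersion
NULL

.SPECTRUM_ROLES <- c("od", "delta_od_diag", "epsilon", "pump", "tds", "generic")

#' Spectrum1D: a one-dimensional infrared spectrum
#'
#' The central 1D container: a strictly increasing wavenumber axis (cm^-1)
#' with one value per point, a role tag saying what the values mean
#' (linear optical density, 2D IR diagonal \eqn{\Delta}OD, extinction
#' coefficient, pump intensity, transition dipole strength, or generic), a
#' per-point validity mask, and free-form provenance metadata. Units are
#' role-dependent: OD and \eqn{\Delta}OD are dimensionless, extinction is in
#' M^-1 cm^-1, pump intensity is in arbitrary units, TDS is in debye squared
#' (D^2).
#'
#' Masked (invalid) points carry \code{NA} values; valid points are always
#' finite. Operations propagate masks: a point invalid in any operand is
#' invalid in the result.
#'
#' @slot axis numeric, strictly increasing, finite, positive wavenumbers.
#' @slot values numeric, same length as \code{axis}; finite wherever
#'   \code{mask} is \code{TRUE}.
#' @slot role character scalar, one of \code{"od"}, \code{"delta_od_diag"},
#'   \code{"epsilon"}, \code{"pump"}, \code{"tds"}, \code{"generic"}.
#' @slot mask logical, \code{TRUE} where the point is valid.
#' @slot meta named list of provenance entries.
#'
#' @seealso [spectrum1d()], [readSpectrum1D()], [waveAxis()], [specValues()]
#' @exportClass Spectrum1D
setClass("Spectrum1D",
  representation(
    axis = "numeric",
    values = "numeric",
    role = "character",
    mask = "logical",
    meta = "list"
  )
)

setValidity("Spectrum1D", function(object) {
  n <- length(object@axis)
  msgs <- character()
  if (n < 3L)
    msgs <- c(msgs, "axis must have at least 3 points")
  if (length(object@values) != n)
    msgs <- c(msgs, "values must have the same length as axis")
  if (length(object@mask) != n)
    msgs <- c(msgs, "mask must have the same length as axis")
  if (!all(is.finite(object@axis)) || any(object@axis <= 0))
    msgs <- c(msgs, "axis values must be finite and positive")
  if (n >= 2L && any(diff(object@axis) <= 0))
    msgs <- c(msgs, "axis must be strictly increasing")
  if (length(object@role) != 1L || !(object@role %in% .SPECTRUM_ROLES))
    msgs <- c(msgs, paste0("role must be one of: ",
                           paste(.SPECTRUM_ROLES, collapse = ", ")))
  if (anyNA(object@mask))
    msgs <- c(msgs, "mask must not contain NA")
  if (length(object@mask) == n && !all(is.finite(object@values[object@mask])))
    msgs <- c(msgs, "values must be finite at unmasked points")
  if (length(msgs)) msgs else TRUE
})

#' TDSSpectrum: a transition-dipole-strength spectrum
#'
#' A [Spectrum1D-class] whose values are dipole strengths d(\eqn{\omega}) in
#' D^2 (role \code{"tds"}). Unmasked values are nonnegative; the mask is
#' \code{FALSE} wherever the corrected-OD floor guard suppressed the
#' calculation (near-zero OD would otherwise blow up the \eqn{\Delta}OD/OD
#' ratio into large noise artifacts).
#'
#' @seealso [computeTDS()], [tdsAt()]
#' @exportClass TDSSpectrum
setClass("TDSSpectrum", contains = "Spectrum1D")

setValidity("TDSSpectrum", function(object) {
  msgs <- character()
  if (object@role != "tds")
    msgs <- c(msgs, "role must be 'tds'")
  if (any(object@values[object@mask] < 0))
    msgs <- c(msgs, "unmasked TDS values must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Spectrum2D: a pump-by-probe 2D IR spectrum
#'
#' The \eqn{\Delta}OD surface of a 2D IR measurement: rows indexed by the
#' pump axis, columns by the probe axis, both strictly increasing
#' wavenumbers in cm^-1.
#'
#' @slot pumpAxis numeric, strictly increasing pump wavenumbers.
#' @slot probeAxis numeric, strictly increasing probe wavenumbers.
#' @slot signal numeric matrix, \code{length(pumpAxis)} rows by
#'   \code{length(probeAxis)} columns, all finite.
#' @slot meta named list of provenance entries.
#'
#' @seealso [spectrum2d()], [readSpectrum2D()], [extractDiagonal()]
#' @exportClass Spectrum2D
setClass("Spectrum2D",
  representation(
    pumpAxis = "numeric",
    probeAxis = "numeric",
    signal = "matrix",
    meta = "list"
  )
)

setValidity("Spectrum2D", function(object) {
  msgs <- character()
  if (length(object@pumpAxis) < 2L || length(object@probeAxis) < 2L)
    msgs <- c(msgs, "both axes need at least 2 points")
  if (!all(is.finite(object@pumpAxis)) || any(diff(object@pumpAxis) <= 0))
    msgs <- c(msgs, "pump axis must be finite and strictly increasing")
  if (!all(is.finite(object@probeAxis)) || any(diff(object@probeAxis) <= 0))
    msgs <- c(msgs, "probe axis must be finite and strictly increasing")
  if (!is.numeric(object@signal))
    msgs <- c(msgs, "signal must be numeric")
  if (nrow(object@signal) != length(object@pumpAxis) ||
      ncol(object@signal) != length(object@probeAxis))
    msgs <- c(msgs, "signal dimensions must match axis lengths (pump x probe)")
  if (!all(is.finite(object@signal)))
    msgs <- c(msgs, "signal entries must all be finite")
  if (length(msgs)) msgs else TRUE
})

#' BaselineResult: diagnostics of a baseline fit
#'
#' Holds the fitted baseline for a signal together with the diagnostics of
#' how it was obtained. For airPLS these are the adaptive weights at the
#' final iteration, the iteration count, whether the 0.1\% termination
#' criterion was reached, and the residual-norm ratio |d|/|s| at
#' termination; for polynomial fits the weights are the 0/1 indicator of
#' points inside the fit ranges.
#'
#' @slot baseline numeric, same length and units as the input signal.
#' @slot weights numeric in [0, 1].
#' @slot iterations integer iteration count.
#' @slot converged logical; \code{TRUE} iff the termination ratio was
#'   reached before the iteration cap.
#' @slot residualNormRatio numeric, |d|/|s| at termination (L1 norms).
#' @slot lambda numeric smoothness penalty (airPLS/Whittaker), \code{NA}
#'   for polynomial fits.
#' @slot method character, \code{"airpls"} or \code{"polynomial"}.
#' @slot meta named list (fit parameters, ranges, smoothing record).
#'
#' @seealso [airPLS()], [polynomialBaseline()], [correctBaseline()]
#' @exportClass BaselineResult
setClass("BaselineResult",
  representation(
    baseline = "numeric",
    weights = "numeric",
    iterations = "integer",
    converged = "logical",
    residualNormRatio = "numeric",
    lambda = "numeric",
    method = "character",
    meta = "list"
  )
)

setValidity("BaselineResult", function(object) {
  msgs <- character()
  if (length(object@weights) != length(object@baseline))
    msgs <- c(msgs, "weights must match baseline length")
  if (any(object@weights < 0 | object@weights > 1, na.rm = TRUE))
    msgs <- c(msgs, "weights must lie in [0, 1]")
  if (length(object@iterations) != 1L || object@iterations < 0L)
    msgs <- c(msgs, "iterations must be a single nonnegative integer")
  if (length(msgs)) msgs else TRUE
})

#' CalibrantReference: the calibrant side of the TDS equation
#'
#' A calibrant is a small molecule with an independently established dipole
#' strength (e.g. N-methylacetamide near 1623 cm^-1, or
#' 2-hydroxy-5-nitrobenzaldehyde at 1585 cm^-1). The TDS equation scales the
#' sample \eqn{\Delta}OD/OD ratio by the calibrant's ratio at its band
#' maximum and by its known \eqn{|\mu|^2}.
#'
#' @slot name character label.
#' @slot omegaMax wavenumber (cm^-1) of the calibrant band maximum.
#' @slot mu2 known dipole strength \eqn{|\mu|^2_{cal}} in D^2, > 0.
#' @slot ratioAtMax \eqn{\Delta OD_{cal}(\omega_{max})/OD_{cal}(\omega_{max})},
#'   dimensionless, > 0.
#'
#' @seealso [calibrantReference()], [calibrantFromSpectra()], [computeTDS()]
#' @exportClass CalibrantReference
setClass("CalibrantReference",
  representation(
    name = "character",
    omegaMax = "numeric",
    mu2 = "numeric",
    ratioAtMax = "numeric"
  )
)

setValidity("CalibrantReference", function(object) {
  msgs <- character()
  if (length(object@mu2) != 1L || !is.finite(object@mu2) || object@mu2 <= 0)
    msgs <- c(msgs, "mu2 must be a single positive number (D^2)")
  if (length(object@ratioAtMax) != 1L || !is.finite(object@ratioAtMax) ||
      object@ratioAtMax <= 0)
    msgs <- c(msgs, "ratioAtMax must be a single positive number")
  if (length(object@omegaMax) != 1L || !is.finite(object@omegaMax) ||
      object@omegaMax <= 0)
    msgs <- c(msgs, "omegaMax must be a single positive wavenumber")
  if (length(msgs)) msgs else TRUE
})

#' PeakBounds: integration limits of an absorption band
#'
#' Lower and upper wavenumber limits for band integration, found from
#' zero-crossings of the smoothed first-derivative spectrum (or the
#' derivative-magnitude floor fallback), plus the band maximum.
#'
#' @slot lo,hi numeric wavenumbers (cm^-1), \code{lo < center < hi}.
#' @slot center numeric wavenumber of the band maximum.
#'
#' @seealso [findPeakBounds()], [dipoleStrengthFTIR()]
#' @exportClass PeakBounds
setClass("PeakBounds",
  representation(lo = "numeric", hi = "numeric", center = "numeric")
)

setValidity("PeakBounds", function(object) {
  if (!(object@lo < object@center && object@center < object@hi))
    "requires lo < center < hi" else TRUE
})

#' DipoleStrength: a single dipole-strength readout
#'
#' One transition dipole strength in D^2, tagged with the method that
#' produced it (FTIR band integration or 2D IR TDS) and the wavenumber of
#' the mode evaluated.
#'
#' @slot value numeric, D^2, >= 0.
#' @slot method character, \code{"ftir_eq1"} or \code{"tds_eq2"}.
#' @slot frequency numeric wavenumber (cm^-1).
#'
#' @seealso [dipoleStrengthFTIR()], [tdsAt()], [averageReplicates()]
#' @exportClass DipoleStrength
setClass("DipoleStrength",
  representation(value = "numeric", method = "character",
                 frequency = "numeric")
)

setValidity("DipoleStrength", function(object) {
  msgs <- character()
  if (length(object@value) != 1L || !is.finite(object@value) ||
      object@value < 0)
    msgs <- c(msgs, "value must be a single nonnegative number (D^2)")
  if (!(object@method %in% c("ftir_eq1", "tds_eq2")))
    msgs <- c(msgs, "method must be 'ftir_eq1' or 'tds_eq2'")
  if (length(msgs)) msgs else TRUE
})

#' SpectrumSeries: a time series of spectra
#'
#' An ordered set of spectra acquired during a kinetics experiment
#' (e.g. one 2D IR spectrum every 66 s throughout amyloid aggregation).
#' Frames are either [Spectrum1D-class] diagonal slices or full
#' [Spectrum2D-class] surfaces, all on a common axis.
#'
#' @slot times numeric, seconds since the start of the experiment, strictly
#'   increasing, one per frame.
#' @slot frames list of spectra sharing axes.
#' @slot cadence numeric, nominal seconds per frame.
#' @slot meta named list (e.g. \code{startOffset} for the delay between
#'   initiating aggregation and the first frame).
#'
#' @seealso [spectrumSeries()], [windowAverage()], [intensityTrace()]
#' @exportClass SpectrumSeries
setClass("SpectrumSeries",
  representation(
    times = "numeric",
    frames = "list",
    cadence = "numeric",
    meta = "list"
  )
)

setValidity("SpectrumSeries", function(object) {
  msgs <- character()
  if (length(object@frames) == 0L)
    msgs <- c(msgs, "series must contain at least one frame")
  if (length(object@times) != length(object@frames))
    msgs <- c(msgs, "times length must equal frame count")
  if (length(object@times) >= 2L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  ok1d <- all(vapply(object@frames, is, logical(1), class2 = "Spectrum1D"))
  ok2d <- all(vapply(object@frames, is, logical(1), class2 = "Spectrum2D"))
  if (!(ok1d || ok2d))
    msgs <- c(msgs, "frames must all be Spectrum1D or all Spectrum2D")
  if (ok1d && length(object@frames) > 1L) {
    ax <- object@frames[[1L]]@axis
    same <- vapply(object@frames, function(f)
      length(f@axis) == length(ax) && all(f@axis == ax), logical(1))
    if (!all(same)) msgs <- c(msgs, "frames must share a common axis")
  }
  if (length(msgs)) msgs else TRUE
})

#' KineticsTrace: a per-window kinetics readout
#'
#' Times (window midpoints, seconds) with one value per window: either the
#' diagonal \eqn{|\Delta OD|} intensity at a probe frequency or the TDS in
#' D^2. Windows whose readout fell on a masked TDS point carry \code{NA}
#' values (never silently dropped).
#'
#' @slot times numeric seconds, strictly increasing.
#' @slot values numeric, same length as times (\code{NA} = masked window).
#' @slot kind character, \code{"intensity"} or \code{"tds"}.
#' @slot frequency numeric wavenumber probed (cm^-1).
#' @slot meta named list.
#'
#' @seealso [intensityTrace()], [tdsTrace()]
#' @exportClass KineticsTrace
setClass("KineticsTrace",
  representation(
    times = "numeric",
    values = "numeric",
    kind = "character",
    frequency = "numeric",
    meta = "list"
  )
)

setValidity("KineticsTrace", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@values))
    msgs <- c(msgs, "times and values must have equal length")
  if (length(object@times) >= 2L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (!(object@kind %in% c("intensity", "tds")))
    msgs <- c(msgs, "kind must be 'intensity' or 'tds'")
  if (length(msgs)) msgs else TRUE
})

#' SNRReport: signal-to-noise assessment of a corrected spectrum
#'
#' Peak-height-over-noise-sd signal-to-noise ratio: the signal height is the
#' maximum inside the signal window, the noise sd is the standard deviation
#' in a peak-free noise window after removing a linear trend across it.
#'
#' @slot snr numeric, \code{signalHeight / noiseSd}.
#' @slot signalHeight,noiseSd numeric, in the units of the spectrum.
#' @slot signalWindow,noiseWindow numeric length-2 wavenumber intervals.
#'
#' @seealso [snrReport()]
#' @exportClass SNRReport
setClass("SNRReport",
  representation(
    snr = "numeric",
    signalHeight = "numeric",
    noiseSd = "numeric",
    signalWindow = "numeric",
    noiseWindow = "numeric"
  )
)

setValidity("SNRReport", function(object) {
  msgs <- character()
  if (!(object@noiseSd > 0))
    msgs <- c(msgs, "noiseSd must be positive")
  if (abs(object@snr - object@signalHeight / object@noiseSd) >
      1e-9 * max(1, abs(object@snr)))
    msgs <- c(msgs, "snr must equal signalHeight / noiseSd")
  if (length(msgs)) msgs else TRUE
})

#' GrubbsResult: single-outlier Grubbs' test
#'
#' Two-sided, single-outlier Grubbs' test: G is the maximum studentized
#' absolute deviation from the sample mean; the critical value comes from
#' the t distribution with n - 2 degrees of freedom at level
#' \eqn{\alpha/(2n)}. \code{outlierIndex} is set iff G exceeds the critical
#' value, and is \code{NA} otherwise.
#'
#' @slot statistic numeric G >= 0.
#' @slot critical numeric critical value.
#' @slot alpha numeric significance level.
#' @slot outlierIndex integer index of the flagged value, or \code{NA}.
#' @slot n integer sample size.
#'
#' @seealso [grubbsTest()]
#' @exportClass GrubbsResult
setClass("GrubbsResult",
  representation(
    statistic = "numeric",
    critical = "numeric",
    alpha = "numeric",
    outlierIndex = "integer",
    n = "integer"
  )
)

setValidity("GrubbsResult", function(object) {
  msgs <- character()
  if (object@statistic < 0)
    msgs <- c(msgs, "statistic must be nonnegative")
  flagged <- !is.na(object@outlierIndex)
  if (flagged != (object@statistic > object@critical))
    msgs <- c(msgs, "outlierIndex must be set iff statistic > critical")
  if (length(msgs)) msgs else TRUE
})
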