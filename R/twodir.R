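#' Pointwise delta-OD / OD ratio with a near-zero-OD guard
#'
#' Computes \eqn{\Delta OD(\omega,\omega)/OD(\omega)} across the spectral
#' region of interest. Wherever the corrected OD falls below
#' \code{odFloorFraction} times its maximum, the ratio is masked rather than
#' computed: dividing by a near-zero corrected OD is what produces the
#' large noise artifacts seen in TDS spectra when the baseline crosses
#' zero, and masking makes that failure explicit instead of propagating it.
#'
#' @param deltaODDiag [Spectrum1D-class] diagonal magnitudes (role
#'   \code{"delta_od_diag"}); negative entries are treated as magnitudes.
#' @param odCorrected [Spectrum1D-class], baseline-corrected linear OD on
#'   the same axis.
#' @param odFloorFraction OD floor as a fraction of \code{max(od)}
#'   (default 0.01).
#' @return a masked [Spectrum1D-class] of ratios (role \code{"generic"}).
#' @export
ratioSpectrum <- function(deltaODDiag, odCorrected, odFloorFraction = 0.01) {
  .checkCommonAxis(deltaODDiag, odCorrected, "delta-OD and OD spectra")
  dod <- abs(deltaODDiag@values)
  od <- odCorrected@values
  mask <- deltaODDiag@mask & odCorrected@mask
  maxOD <- suppressWarnings(max(od[mask], na.rm = TRUE))
  if (!is.finite(maxOD) || maxOD <= 0)
    tdsStop("tds_data_error",
            "corrected OD is nowhere positive: no ratio can be computed")
  floorv <- odFloorFraction * maxOD
  mask <- mask & !is.na(od) & od >= floorv & od > 0
  if (!any(mask))
    tdsStop("tds_data_error",
            "all points fall below the OD floor: no ratio can be computed")
  vals <- rep(NA_real_, length(od))
  vals[mask] <- dod[mask] / od[mask]
  spectrum1d(deltaODDiag@axis, vals, role = "generic", mask = mask,
             meta = list(od_floor_fraction = odFloorFraction,
                         od_floor = floorv))
}

#' Construct a calibrant reference directly
#'
#' @param name calibrant label (e.g. \code{"NMA"}, \code{"2H5NBA"}).
#' @param omegaMax band-maximum wavenumber (cm^-1).
#' @param mu2 known \eqn{|\mu|^2} in D^2.
#' @param ratioAtMax \eqn{\Delta}OD/OD measured at \code{omegaMax}.
#' @return a [CalibrantReference-class].
#' @seealso [calibrantFromSpectra()]
#' @export
calibrantReference <- function(name, omegaMax, mu2, ratioAtMax) {
  new("CalibrantReference", name = name, omegaMax = omegaMax, mu2 = mu2,
      ratioAtMax = ratioAtMax)
}

#' Derive a calibrant reference from its measured spectra
#'
#' Evaluates the calibrant's \eqn{\Delta}OD/OD ratio at the frequency of its
#' band maximum (\eqn{\omega_{max}} = argmax of the baseline-corrected
#' linear OD when \code{omegaMax = "auto"}), pairing it with the
#' independently known dipole strength \code{mu2}.
#'
#' @param deltaODCal,odCal [Spectrum1D-class] calibrant spectra on a common
#'   axis, baseline-corrected.
#' @param mu2 established calibrant dipole strength (D^2), > 0.
#' @param omegaMax \code{"auto"} (default) or an explicit wavenumber.
#' @param name calibrant label.
#' @return a [CalibrantReference-class].
#' @export
calibrantFromSpectra <- function(deltaODCal, odCal, mu2, omegaMax = "auto",
                                 name = "calibrant") {
  .checkCommonAxis(deltaODCal, odCal, "calibrant spectra")
  if (!is.numeric(mu2) || length(mu2) != 1L || !is.finite(mu2) || mu2 <= 0)
    tdsStop("tds_parameter_error", "mu2 must be a single positive number (D^2)")
  if (identical(omegaMax, "auto")) {
    omegaMax <- odCal@axis[which.max(odCal@values)]
  } else {
    omegaMax <- as.numeric(omegaMax)
    if (omegaMax < odCal@axis[1L] || omegaMax > odCal@axis[length(odCal@axis)])
      tdsStop("tds_range_error", "omegaMax lies outside the calibrant axis")
  }
  dodMax <- approx(deltaODCal@axis, abs(deltaODCal@values), omegaMax)$y
  odMax <- approx(odCal@axis, odCal@values, omegaMax)$y
  if (!is.finite(odMax) || odMax <= 0 || !is.finite(dodMax) || dodMax <= 0)
    tdsStop("tds_data_error",
            "calibrant delta-OD/OD ratio at omegaMax is not positive")
  calibrantReference(name, omegaMax, mu2, dodMax / odMax)
}

#' Pump-intensity normalization factor
#'
#' The factor \eqn{I_{pump}(\omega_{max}) / I_{pump}(\omega)} that corrects
#' the TDS spectrum for the non-flat intensity profile of the pump pulses.
#' \eqn{\omega_{max}} is the calibrant's band-maximum frequency (where the
#' calibrant ratio was evaluated), not the maximum of the pump envelope: the
#' factor must equal 1 exactly at the frequency the calibration was
#' performed. The correction is typically negligible for modes within
#' ~20 cm^-1 of the calibrant but matters across the full amide I' range.
#'
#' @param pump [Spectrum1D-class] pump intensity, strictly positive over
#'   \code{targetAxis} and at \code{omegaMax}.
#' @param omegaMax calibrant band-maximum wavenumber (cm^-1).
#' @param targetAxis wavenumbers at which to evaluate the factor.
#' @return a [Spectrum1D-class] of factors on \code{targetAxis}.
#' @export
pumpNormFactor <- function(pump, omegaMax, targetAxis) {
  rng <- range(pump@axis)
  if (omegaMax < rng[1L] || omegaMax > rng[2L])
    tdsStop("tds_range_error", "omegaMax lies outside the pump axis")
  if (any(targetAxis < rng[1L] | targetAxis > rng[2L]))
    tdsStop("tds_range_error", "targetAxis extends outside the pump axis")
  iMax <- approx(pump@axis, pump@values, omegaMax)$y
  iAt <- approx(pump@axis, pump@values, targetAxis)$y
  if (!is.finite(iMax) || iMax <= 0 || any(!is.finite(iAt) | iAt <= 0))
    tdsStop("tds_domain_error", "pump intensity must be strictly positive")
  spectrum1d(targetAxis, iMax / iAt, role = "generic",
             meta = list(pump_omega_max = omegaMax))
}

#' Compute a transition-dipole-strength spectrum
#'
#' Assembles the TDS spectrum from the 2D IR diagonal and the corrected
#' linear OD:
#' \deqn{d(\omega) = \frac{\Delta OD_{s}(\omega,\omega)/OD_{s}(\omega)}
#'   {\Delta OD_{cal}(\omega_{max})/OD_{cal}(\omega_{max})}
#'   \cdot |\mu|^2_{cal}
#'   \cdot \frac{I_{pump}(\omega_{max})}{I_{pump}(\omega)},}
#' where the final pump factor is applied only when
#' \code{normalizePump = TRUE}. Points suppressed by the OD floor guard stay
#' masked; all parameter choices are recorded in the result's metadata, and
#' the corrected OD is carried along so that [tdsAt()] can locate band
#' maxima.
#'
#' @param sampleDeltaODDiag [Spectrum1D-class], diagonal magnitudes.
#' @param sampleODCorrected [Spectrum1D-class], baseline-corrected linear
#'   OD on the same axis.
#' @param calibrant a [CalibrantReference-class].
#' @param pump [Spectrum1D-class] pump intensity (required when
#'   \code{normalizePump = TRUE}; its axis must cover the sample axis and
#'   the calibrant \eqn{\omega_{max}}).
#' @param normalizePump apply the pump-intensity factor (default
#'   \code{FALSE}).
#' @param odFloorFraction OD floor for the ratio guard (default 0.01).
#' @return a [TDSSpectrum-class] in D^2.
#' @examples
#' x <- seq(1500, 1750, by = 0.5)
#' ds <- synthDataset(synthConfig(noiseSdOD = 0, noiseSd2D = 0,
#'                                baselineCoeffs = 0))
#' cal <- calibrantFromSpectra(ds$calibrantDiag, ds$calibrantOD, mu2 = 0.12)
#' tds <- computeTDS(ds$diag, ds$od, cal, pump = ds$pump,
#'                   normalizePump = TRUE)
#' tdsAt(tds, 1623)
#' @export
computeTDS <- function(sampleDeltaODDiag, sampleODCorrected, calibrant,
                       pump = NULL, normalizePump = FALSE,
                       odFloorFraction = 0.01) {
  if (normalizePump && is.null(pump))
    tdsStop("tds_parameter_error",
            "normalizePump = TRUE requires a pump spectrum")
  ratio <- ratioSpectrum(sampleDeltaODDiag, sampleODCorrected,
                         odFloorFraction)
  d <- ratio@values / calibrant@ratioAtMax * calibrant@mu2
  if (normalizePump) {
    fac <- pumpNormFactor(pump, calibrant@omegaMax, ratio@axis)
    d <- d * fac@values
  }
  new("TDSSpectrum",
      spectrum1d(ratio@axis, d, role = "tds", mask = ratio@mask,
                 meta = list(calibrant = calibrant@name,
                             calibrant_mu2 = calibrant@mu2,
                             calibrant_omega_max = calibrant@omegaMax,
                             pump_normalized = normalizePump,
                             od_floor_fraction = odFloorFraction,
                             od_corrected = sampleODCorrected@values)))
}

#' Read a dipole strength off a TDS spectrum
#'
#' @param tds a [TDSSpectrum-class] produced by [computeTDS()].
#' @param omega wavenumber of interest (cm^-1).
#' @param mode \code{"nearest"} (value at the nearest axis point, default)
#'   or \code{"local_max"} (value at the maximum of the corrected OD within
#'   \code{window}, i.e. at the band maximum).
#' @param window length-2 interval for \code{"local_max"} (defaults to
#'   \eqn{\pm}10 cm^-1 around \code{omega}).
#' @return a [DipoleStrength-class] (method \code{"tds_eq2"}); reading a
#'   masked point raises a masked-value error.
#' @export
tdsAt <- function(tds, omega, mode = c("nearest", "local_max"),
                  window = NULL) {
  mode <- match.arg(mode)
  x <- tds@axis
  if (omega < x[1L] || omega > x[length(x)])
    tdsStop("tds_range_error", "omega lies outside the TDS axis")
  if (mode == "nearest") {
    i <- which.min(abs(x - omega))
  } else {
    od <- tds@meta$od_corrected
    if (is.null(od))
      tdsStop("tds_parameter_error",
              "local_max mode needs the corrected OD recorded in the TDS metadata")
    if (is.null(window)) window <- c(omega - 10, omega + 10)
    inWin <- which(x >= min(window) & x <= max(window))
    if (!length(inWin))
      tdsStop("tds_range_error", "window contains no axis points")
    i <- inWin[which.max(od[inWin])]
  }
  if (!tds@mask[i])
    tdsStop("tds_masked_error",
            sprintf("TDS value at %.6g cm-1 is masked (OD floor guard)", x[i]))
  new("DipoleStrength", value = tds@values[i], method = "tds_eq2",
      frequency = x[i])
}
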