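#' Construct a Spectrum1D
#'
#' Builds a validated [Spectrum1D-class]. Points are sorted by ascending
#' wavenumber; duplicate wavenumbers are rejected. Masked points may carry
#' \code{NA} values.
#'
#' @param axis numeric wavenumbers (cm^-1), finite and positive.
#' @param values numeric values, one per axis point.
#' @param role role tag; one of \code{"od"}, \code{"delta_od_diag"},
#'   \code{"epsilon"}, \code{"pump"}, \code{"tds"}, \code{"generic"}.
#' @param mask logical validity mask (default: all valid).
#' @param meta named list of provenance entries.
#' @return a [Spectrum1D-class].
#' @examples
#' spectrum1d(c(1600, 1610, 1620), c(0.1, 0.2, 0.3), role = "od")
#' @export
spectrum1d <- function(axis, values, role = "generic",
                       mask = rep(TRUE, length(axis)), meta = list()) {
  axis <- as.numeric(axis); values <- as.numeric(values)
  if (length(axis) < 3L)
    tdsStop("tds_size_error",
            sprintf("spectrum needs at least 3 points, got %d", length(axis)))
  if (anyDuplicated(axis))
    tdsStop("tds_duplicate_axis_error",
            sprintf("duplicate wavenumber value(s): %s",
                    paste(unique(axis[duplicated(axis)]), collapse = ", ")))
  ord <- order(axis)
  new("Spectrum1D", axis = axis[ord], values = values[ord], role = role,
      mask = as.logical(mask)[ord], meta = meta)
}

#' Construct a Spectrum2D
#'
#' Builds a validated [Spectrum2D-class]; axes are sorted ascending with the
#' signal rows/columns permuted accordingly.
#'
#' @param pumpAxis,probeAxis numeric wavenumbers (cm^-1).
#' @param signal numeric matrix, pump rows by probe columns.
#' @param meta named list.
#' @return a [Spectrum2D-class].
#' @export
spectrum2d <- function(pumpAxis, probeAxis, signal, meta = list()) {
  op <- order(pumpAxis); oq <- order(probeAxis)
  new("Spectrum2D", pumpAxis = as.numeric(pumpAxis)[op],
      probeAxis = as.numeric(probeAxis)[oq],
      signal = as.matrix(signal)[op, oq, drop = FALSE], meta = meta)
}

#' @rdname accessors
setMethod("waveAxis", "Spectrum1D", function(x) x@axis)
#' @rdname accessors
setMethod("specValues", "Spectrum1D", function(x) x@values)
#' @rdname accessors
setMethod("specRole", "Spectrum1D", function(x) x@role)
#' @rdname accessors
setMethod("validMask", "Spectrum1D", function(x) x@mask)
#' @rdname accessors
setMethod("specMeta", "Spectrum1D", function(x) x@meta)

#' @rdname accessors
setMethod("specMeta", "SpectrumSeries", function(x) x@meta)
#' @rdname accessors
setMethod("specMeta", "KineticsTrace", function(x) x@meta)

#' @rdname accessors
setMethod("pumpAxis", "Spectrum2D", function(x) x@pumpAxis)
#' @rdname accessors
setMethod("probeAxis", "Spectrum2D", function(x) x@probeAxis)
#' @rdname accessors
setMethod("signalMatrix", "Spectrum2D", function(x) x@signal)
#' @rdname accessors
setMethod("specMeta", "Spectrum2D", function(x) x@meta)

setMethod("length", "Spectrum1D", function(x) length(x@axis))

setMethod("show", "Spectrum1D", function(object) {
  nm <- sum(!object@mask)
  cat(sprintf("%s of length %d [%s]\n", class(object), length(object@axis),
              object@role))
  cat(sprintf("  axis: %.6g .. %.6g cm-1 (step ~%.4g)\n",
              object@axis[1L], object@axis[length(object@axis)],
              median(diff(object@axis))))
  rng <- range(object@values[object@mask])
  cat(sprintf("  values: %.6g .. %.6g%s\n", rng[1L], rng[2L],
              if (nm) sprintf("  (%d masked)", nm) else ""))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "Spectrum2D", function(object) {
  cat(sprintf("Spectrum2D %d (pump) x %d (probe)\n",
              length(object@pumpAxis), length(object@probeAxis)))
  cat(sprintf("  pump:  %.6g .. %.6g cm-1\n", object@pumpAxis[1L],
              object@pumpAxis[length(object@pumpAxis)]))
  cat(sprintf("  probe: %.6g .. %.6g cm-1\n", object@probeAxis[1L],
              object@probeAxis[length(object@probeAxis)]))
  cat(sprintf("  signal: %.4g .. %.4g\n", min(object@signal),
              max(object@signal)))
  invisible(NULL)
})

setMethod("show", "BaselineResult", function(object) {
  cat(sprintf("BaselineResult [%s]: %d point(s), %d iteration(s), %s\n",
              object@method, length(object@baseline), object@iterations,
              if (isTRUE(object@converged)) "converged" else "not converged"))
  if (is.finite(object@lambda))
    cat(sprintf("  lambda = %g\n", object@lambda))
  cat(sprintf("  |d|/|s| at termination = %.4g\n", object@residualNormRatio))
  invisible(NULL)
})

setMethod("show", "CalibrantReference", function(object) {
  cat(sprintf("CalibrantReference '%s': omega_max = %.6g cm-1, |mu|^2 = %.4g D^2, dOD/OD at max = %.6g\n",
              object@name, object@omegaMax, object@mu2, object@ratioAtMax))
  invisible(NULL)
})

setMethod("show", "DipoleStrength", function(object) {
  cat(sprintf("DipoleStrength: %.4g D^2 at %.6g cm-1 [%s]\n",
              object@value, object@frequency, object@method))
  invisible(NULL)
})

setMethod("show", "PeakBounds", function(object) {
  cat(sprintf("PeakBounds: [%.6g, %.6g] cm-1, center %.6g cm-1\n",
              object@lo, object@hi, object@center))
  invisible(NULL)
})

setMethod("show", "SpectrumSeries", function(object) {
  cat(sprintf("SpectrumSeries: %d frame(s) of %s, t = %.5g .. %.5g s (cadence %.4g s)\n",
              length(object@frames), class(object@frames[[1L]]),
              object@times[1L], object@times[length(object@times)],
              object@cadence))
  invisible(NULL)
})

setMethod("show", "KineticsTrace", function(object) {
  cat(sprintf("KineticsTrace [%s] at %.6g cm-1: %d window(s)%s\n",
              object@kind, object@frequency, length(object@times),
              if (anyNA(object@values))
                sprintf(" (%d masked)", sum(is.na(object@values))) else ""))
  invisible(NULL)
})

setMethod("show", "SNRReport", function(object) {
  cat(sprintf("SNR = %.4g (signal height %.4g / noise sd %.4g)\n",
              object@snr, object@signalHeight, object@noiseSd))
  invisible(NULL)
})

setMethod("show", "GrubbsResult", function(object) {
  cat(sprintf("Grubbs' test (two-sided, n = %d, alpha = %g): G = %.4f, critical = %.4f\n",
              object@n, object@alpha, object@statistic, object@critical))
  if (is.na(object@outlierIndex)) cat("  no outlier detected\n")
  else cat(sprintf("  value %d is an outlier\n", object@outlierIndex))
  invisible(NULL)
})

## internal: require two spectra to share an axis exactly
.checkCommonAxis <- function(a, b, what = "spectra") {
  if (length(a@axis) != length(b@axis) || any(a@axis != b@axis))
    tdsStop("tds_range_error",
            sprintf("%s must share a common axis (resample first)", what))
  invisible(NULL)
}

#' Resample a spectrum onto a target axis
#'
#' Linear interpolation onto \code{targetAxis}. Extrapolation is never
#' performed: every target point must lie inside the spectrum's axis range.
#' Masks propagate: a target point is masked if either bracketing source
#' point is masked. Role and metadata are preserved.
#'
#' @param spec a [Spectrum1D-class].
#' @param targetAxis numeric wavenumbers inside
#'   \code{range(waveAxis(spec))}.
#' @return a [Spectrum1D-class] on \code{targetAxis}.
#' @examples
#' s <- spectrum1d(seq(1600, 1700, by = 5), seq(0, 1, length.out = 21))
#' resampleToAxis(s, c(1602.5, 1650, 1697.5))
#' @export
resampleToAxis <- function(spec, targetAxis) {
  targetAxis <- sort(as.numeric(targetAxis))
  rng <- range(spec@axis)
  if (any(targetAxis < rng[1L] | targetAxis > rng[2L]))
    tdsStop("tds_range_error",
            sprintf("target axis [%g, %g] extends outside spectrum range [%g, %g]; extrapolation is not supported",
                    min(targetAxis), max(targetAxis), rng[1L], rng[2L]))
  ## a target point is valid only if every source point it interpolates
  ## from is valid (approx() would otherwise bridge masked gaps silently)
  mask <- approx(spec@axis, as.numeric(spec@mask), xout = targetAxis,
                 method = "linear", ties = "ordered")$y >= 1
  vals <- spec@values
  vals[!spec@mask] <- NA_real_
  y <- suppressWarnings(
    approx(spec@axis[spec@mask], vals[spec@mask], xout = targetAxis,
           method = "linear", ties = "ordered")$y)
  y[!mask] <- NA_real_
  spectrum1d(targetAxis, y, role = spec@role, mask = mask, meta = spec@meta)
}

#' Convert transmission spectra to optical density
#'
#' OD = -log10(sample / reference), pointwise, as used to derive the linear
#' optical density from the transmission of the 2D IR probe pulse.
#'
#' @param sampleIntensity,referenceIntensity [Spectrum1D-class] transmission
#'   intensities on a common axis, strictly positive.
#' @return a [Spectrum1D-class] with role \code{"od"}.
#' @export
transmissionToOD <- function(sampleIntensity, referenceIntensity) {
  .checkCommonAxis(sampleIntensity, referenceIntensity,
                   "sample and reference intensities")
  mask <- sampleIntensity@mask & referenceIntensity@mask
  s <- sampleIntensity@values; r <- referenceIntensity@values
  if (any(s[mask] <= 0) || any(r[mask] <= 0))
    tdsStop("tds_domain_error",
            "transmission intensities must be strictly positive")
  od <- rep(NA_real_, length(s))
  od[mask] <- -log10(s[mask] / r[mask])
  spectrum1d(sampleIntensity@axis, od, role = "od", mask = mask,
             meta = c(sampleIntensity@meta, list(od_from = "transmission")))
}

#' Subtract a solvent background spectrum
#'
#' Removes a (scaled) solvent background from the sample's linear OD, e.g.
#' a deuterated Tris buffer spectrum collected alongside peptide samples.
#'
#' @param sampleOD,solventOD [Spectrum1D-class] on a common axis.
#' @param scale multiplier applied to the solvent before subtraction
#'   (default 1).
#' @return [Spectrum1D-class]: \code{sample - scale * solvent}, with the
#'   solvent provenance recorded in \code{specMeta}.
#' @export
subtractSolvent <- function(sampleOD, solventOD, scale = 1.0) {
  .checkCommonAxis(sampleOD, solventOD, "sample and solvent spectra")
  mask <- sampleOD@mask & solventOD@mask
  vals <- rep(NA_real_, length(sampleOD))
  vals[mask] <- sampleOD@values[mask] - scale * solventOD@values[mask]
  spectrum1d(sampleOD@axis, vals, role = sampleOD@role, mask = mask,
             meta = c(sampleOD@meta,
                      list(solvent_subtracted = TRUE, solvent_scale = scale)))
}
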