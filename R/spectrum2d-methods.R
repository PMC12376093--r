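## bilinear interpolation of a pump x probe matrix at (p, q) pairs
.bilinear <- function(pumpAxis, probeAxis, M, p, q) {
  ip <- findInterval(p, pumpAxis, rightmost.closed = TRUE)
  iq <- findInterval(q, probeAxis, rightmost.closed = TRUE)
  ip <- pmin(pmax(ip, 1L), length(pumpAxis) - 1L)
  iq <- pmin(pmax(iq, 1L), length(probeAxis) - 1L)
  tp <- (p - pumpAxis[ip]) / (pumpAxis[ip + 1L] - pumpAxis[ip])
  tq <- (q - probeAxis[iq]) / (probeAxis[iq + 1L] - probeAxis[iq])
  n <- nrow(M)
  v11 <- M[cbind(ip, iq)]
  v21 <- M[cbind(ip + 1L, iq)]
  v12 <- M[cbind(ip, iq + 1L)]
  v22 <- M[cbind(ip + 1L, iq + 1L)]
  (1 - tp) * (1 - tq) * v11 + tp * (1 - tq) * v21 +
    (1 - tp) * tq * v12 + tp * tq * v22
}

#' Extract the diagonal slice of a 2D IR spectrum
#'
#' The diagonal intensity slice \eqn{\Delta OD(\omega, \omega)} of the pump
#' x probe surface, obtained by bilinear interpolation at
#' \code{(pump = } \eqn{\omega}\code{, probe = }\eqn{\omega}\code{)}.
#'
#' Diagonal fundamental peaks of 2D IR spectra are ground-state bleaches and
#' may be recorded with either sign convention; the TDS ratio requires a
#' positive \eqn{\Delta}OD, so the slice is returned as magnitudes. If the
#' slice genuinely mixes signs (beyond points whose amplitude is within
#' \code{signTolerance} of the slice maximum, which are treated as noise), a
#' data-quality error is raised rather than guessing the convention.
#'
#' @param spec2d a [Spectrum2D-class].
#' @param outAxis numeric wavenumbers at which to evaluate the diagonal, or
#'   \code{"probe"} (default) to use every probe-axis point that lies inside
#'   the pump range.
#' @param signTolerance fraction of the maximum magnitude below which
#'   sign-flipped points are attributed to noise (default 0.01).
#' @return a [Spectrum1D-class] with role \code{"delta_od_diag"}
#'   (nonnegative values).
#' @export
extractDiagonal <- function(spec2d, outAxis = "probe", signTolerance = 0.01) {
  if (identical(outAxis, "probe")) {
    rngP <- range(spec2d@pumpAxis)
    outAxis <- spec2d@probeAxis[spec2d@probeAxis >= rngP[1L] &
                                spec2d@probeAxis <= rngP[2L]]
    if (length(outAxis) < 3L)
      tdsStop("tds_range_error",
              "pump and probe axes overlap at fewer than 3 probe points")
  } else {
    outAxis <- sort(as.numeric(outAxis))
    if (any(outAxis < min(spec2d@pumpAxis) | outAxis > max(spec2d@pumpAxis) |
            outAxis < min(spec2d@probeAxis) | outAxis > max(spec2d@probeAxis)))
      tdsStop("tds_range_error",
              "requested diagonal point(s) outside the pump or probe range")
  }
  d <- .bilinear(spec2d@pumpAxis, spec2d@probeAxis, spec2d@signal,
                 outAxis, outAxis)
  big <- abs(d) > signTolerance * max(abs(d))
  if (any(d[big] > 0) && any(d[big] < 0))
    tdsStop("tds_data_error",
            "diagonal slice mixes signs beyond the amplitude tolerance; cannot infer the bleach sign convention")
  spectrum1d(outAxis, abs(d), role = "delta_od_diag",
             meta = c(spec2d@meta, list(diagonal_of = "Spectrum2D")))
}
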