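#' First-derivative spectrum
#'
#' Central finite differences of the (optionally Savitzky-Golay presmoothed)
#' spectrum with one-sided differences at the edges, handling nonuniform
#' axes. Used to locate band integration limits from zero-crossings.
#'
#' @param spec a [Spectrum1D-class].
#' @param presmooth smooth before differentiating (default \code{TRUE}).
#' @param sgWindow,sgOrder Savitzky-Golay parameters.
#' @return a [Spectrum1D-class] (role \code{"generic"}) of d(value)/d(cm^-1).
#' @export
firstDerivative <- function(spec, presmooth = TRUE, sgWindow = 15L,
                            sgOrder = 3L) {
  x <- spec@axis
  y <- spec@values
  if (presmooth && length(y) >= sgWindow) y <- savgolSmooth(y, sgWindow, sgOrder)
  n <- length(x)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  d[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
  spectrum1d(x, d, role = "generic",
             meta = list(derivative_of = spec@role, presmooth = presmooth))
}

#' Locate band integration limits
#'
#' Finds the beginning and end of an absorption band for numerical
#' integration. The band center is the local maximum nearest
#' \code{centerHint} inside \code{searchWindow}. Walking outward from the
#' center on each side, the bound is placed at whichever comes first:
#' \itemize{
#'   \item a zero-crossing of the smoothed first derivative (excluding the
#'     crossing at the maximum itself) — for the upper side a crossing from
#'     negative back to positive (the valley before a neighboring band), and
#'     symmetrically for the lower side; or
#'   \item the first point of a run of \code{flatRun} consecutive points
#'     where the derivative magnitude stays below \code{derivFloorFrac}
#'     times its in-band maximum on that side — the band has returned to
#'     background.
#' }
#' If neither triggers before the axis edge, a boundary warning is raised
#' and the edge is used. The procedure is deterministic: ties between
#' equally near local maxima resolve to the lower wavenumber.
#'
#' @param spec a [Spectrum1D-class] (baseline-corrected absorption).
#' @param centerHint approximate band position (cm^-1).
#' @param searchWindow length-2 interval containing \code{centerHint}.
#' @param derivFloorFrac derivative-magnitude floor as a fraction of the
#'   in-band maximum (default 0.01).
#' @param flatRun consecutive sub-floor points required (default 3).
#' @param presmooth,sgWindow,sgOrder smoothing of the derivative (see
#'   [firstDerivative()]).
#' @return a [PeakBounds-class].
#' @export
findPeakBounds <- function(spec, centerHint, searchWindow,
                           derivFloorFrac = 0.01, flatRun = 3L,
                           presmooth = TRUE, sgWindow = 15L, sgOrder = 3L) {
  x <- spec@axis; y <- spec@values
  if (centerHint < min(searchWindow) || centerHint > max(searchWindow))
    tdsStop("tds_parameter_error", "centerHint must lie inside searchWindow")
  inWin <- which(x >= min(searchWindow) & x <= max(searchWindow))
  if (length(inWin) < 3L)
    tdsStop("tds_range_error", "searchWindow contains fewer than 3 points")
  ## local maxima within the window (interior of the window)
  cand <- inWin[-c(1L, length(inWin))]
  isMax <- y[cand] >= y[cand - 1L] & y[cand] >= y[cand + 1L] &
    (y[cand] > y[cand - 1L] | y[cand] > y[cand + 1L])
  cand <- cand[isMax]
  if (!length(cand))
    tdsStop("tds_notfound_error",
            sprintf("no local maximum found in [%g, %g]",
                    min(searchWindow), max(searchWindow)))
  ic <- cand[order(abs(x[cand] - centerHint), x[cand])][1L]
  dv <- firstDerivative(spec, presmooth = presmooth, sgWindow = sgWindow,
                        sgOrder = sgOrder)@values
  n <- length(x)
  walk <- function(dir) {  # dir = +1 (upper bound) or -1 (lower bound)
    if (ic + dir < 1L || ic + dir > n) {
      tdsWarn("tds_boundary_warning", "band bound search reached axis edge")
      return(ic)
    }
    idx <- seq(ic + dir, if (dir > 0) n else 1L, by = dir)
    ## in-band derivative maximum on this side: between center and the
    ## nearest search-window edge
    side <- if (dir > 0) idx[x[idx] <= max(searchWindow)]
            else idx[x[idx] >= min(searchWindow)]
    dmax <- if (length(side)) max(abs(dv[side])) else max(abs(dv[idx]))
    floorv <- derivFloorFrac * dmax
    ## the derivative is near zero at the maximum itself, so the stopping
    ## tests arm only after the descending lobe has been traversed
    armed <- FALSE
    run <- 0L
    for (i in idx) {
      desc <- -dir * dv[i]    # positive while descending away from the max
      if (!armed) {
        if (desc > 0.2 * dmax) armed <- TRUE
        next
      }
      if (abs(dv[i]) < floorv) {
        run <- run + 1L
        if (run >= flatRun) return(i - dir * (flatRun - 1L))
      } else run <- 0L
      if (-desc > floorv) return(i)     # crossed zero: valley before neighbor
    }
    tdsWarn("tds_boundary_warning", "band bound search reached axis edge")
    idx[length(idx)]
  }
  ihi <- walk(+1L); ilo <- walk(-1L)
  if (!(ilo < ic && ic < ihi))
    tdsStop("tds_notfound_error", "could not bracket the band around its maximum")
  new("PeakBounds", lo = x[ilo], hi = x[ihi], center = x[ic])
}

#' Dipole strength from an FTIR extinction spectrum
#'
#' Integrates the baseline-corrected extinction coefficient over the band:
#' \deqn{D = 9.184 \times 10^{-3} \int \frac{\epsilon(\nu)}{\nu}\, d\nu,}
#' with \eqn{\epsilon} in M^-1 cm^-1 and \eqn{\nu} in cm^-1, giving D in
#' debye squared. The integral is evaluated by trapezoidal quadrature over
#' \code{[lo, hi]}, with the endpoint values obtained by linear
#' interpolation when the bounds fall between grid points.
#'
#' @param epsilon a [Spectrum1D-class] with role \code{"epsilon"} (or any
#'   baseline-corrected absorption in extinction units).
#' @param bounds a [PeakBounds-class] inside the spectrum axis.
#' @return a [DipoleStrength-class] (method \code{"ftir_eq1"}).
#' @examples
#' x <- seq(1560, 1680, by = 0.25)
#' eps <- spectrum1d(x, 300 * exp(-(x - 1623)^2 / (2 * 8^2)),
#'                   role = "epsilon")
#' b <- new("PeakBounds", lo = 1583, hi = 1663, center = 1623)
#' dipoleStrengthFTIR(eps, b)
#' @export
dipoleStrengthFTIR <- function(epsilon, bounds) {
  x <- epsilon@axis; y <- epsilon@values
  if (bounds@lo < x[1L] || bounds@hi > x[length(x)])
    tdsStop("tds_range_error", "integration bounds outside the spectrum axis")
  keep <- x > bounds@lo & x < bounds@hi
  xi <- c(bounds@lo, x[keep], bounds@hi)
  yi <- c(approx(x, y, bounds@lo)$y, y[keep], approx(x, y, bounds@hi)$y)
  integral <- pracma::trapz(xi, yi / xi)
  if (integral < -1e-9)
    tdsStop("tds_data_error",
            sprintf("band integral is negative (%.3g): baseline quality insufficient",
                    integral))
  new("DipoleStrength", value = 9.184e-3 * max(integral, 0),
      method = "ftir_eq1", frequency = bounds@center)
}

#' Average replicate dipole strengths
#'
#' Arithmetic mean and sample standard deviation (n - 1 divisor) of
#' replicate measurements of the same mode. The population (n divisor)
#' standard deviation is also reported, since published summary tables do
#' not always state the convention. Replicates must share method and
#' frequency.
#'
#' @param values list of [DipoleStrength-class] objects.
#' @param frequencyTol maximum allowed spread in frequency (cm^-1,
#'   default 1).
#' @return list with \code{mean}, \code{sd} (sample, \code{NA} for n = 1),
#'   \code{sdPop}, \code{n}, \code{method}, \code{frequency}.
#' @examples
#' reps <- lapply(c(0.209, 0.222, 0.226), function(v)
#'   new("DipoleStrength", value = v, method = "ftir_eq1", frequency = 1623))
#' averageReplicates(reps)$mean
#' @export
averageReplicates <- function(values, frequencyTol = 1.0) {
  if (!length(values))
    tdsStop("tds_size_error", "need at least one replicate")
  ok <- vapply(values, is, logical(1), class2 = "DipoleStrength")
  if (!all(ok))
    tdsStop("tds_parameter_error", "values must be DipoleStrength objects")
  meth <- vapply(values, function(v) v@method, character(1))
  freq <- vapply(values, function(v) v@frequency, numeric(1))
  if (length(unique(meth)) != 1L)
    tdsStop("tds_consistency_error", "replicates mix methods")
  if (diff(range(freq)) > frequencyTol)
    tdsStop("tds_consistency_error",
            sprintf("replicate frequencies spread over %.3g cm-1 (> %g)",
                    diff(range(freq)), frequencyTol))
  v <- vapply(values, function(d) d@value, numeric(1))
  n <- length(v)
  list(mean = mean(v),
       sd = if (n > 1L) sd(v) else NA_real_,
       sdPop = if (n > 1L) sqrt(mean((v - mean(v))^2)) else NA_real_,
       n = n, method = meth[1L], frequency = mean(freq))
}
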