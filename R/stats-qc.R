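#' Signal-to-noise ratio of a baseline-corrected spectrum
#'
#' Peak-height convention: the signal height is the maximum inside
#' \code{signalWindow}; the noise sd is the standard deviation inside a
#' disjoint, peak-free \code{noiseWindow} after removing a linear trend
#' across it (so residual baseline slope is not counted as noise).
#'
#' @param spec a [Spectrum1D-class].
#' @param signalWindow,noiseWindow length-2 wavenumber intervals inside the
#'   axis; must not overlap; the noise window must contain at least 10
#'   points.
#' @return an [SNRReport-class].
#' @export
snrReport <- function(spec, signalWindow, noiseWindow) {
  signalWindow <- sort(as.numeric(signalWindow))
  noiseWindow <- sort(as.numeric(noiseWindow))
  if (signalWindow[1L] < noiseWindow[2L] && noiseWindow[1L] < signalWindow[2L])
    tdsStop("tds_parameter_error", "signal and noise windows must be disjoint")
  x <- spec@axis; y <- spec@values
  inS <- which(x >= signalWindow[1L] & x <= signalWindow[2L] & spec@mask)
  inN <- which(x >= noiseWindow[1L] & x <= noiseWindow[2L] & spec@mask)
  if (!length(inS))
    tdsStop("tds_range_error", "signal window contains no points")
  if (length(inN) < 10L)
    tdsStop("tds_size_error",
            sprintf("noise window contains %d point(s); need >= 10",
                    length(inN)))
  height <- max(y[inS])
  resid <- lm.fit(cbind(1, x[inN]), y[inN])$residuals
  noiseSd <- sd(resid)
  ## relative guard: numerically-zero residual scatter means the input is
  ## noiseless and any SNR would be meaningless
  if (noiseSd <= 1e-10 * max(abs(height), .Machine$double.xmin))
    tdsStop("tds_degeneracy_error",
            "noise window has (numerically) zero variance: noiseless input")
  new("SNRReport", snr = height / noiseSd, signalHeight = height,
      noiseSd = noiseSd, signalWindow = signalWindow,
      noiseWindow = noiseWindow)
}

#' Percent error relative to a reference value
#'
#' \code{100 * |measured - reference| / |reference|}, the accuracy measure
#' used to compare recovered dipole strengths with an established value.
#'
#' @param measured,reference numeric; \code{reference} must be nonzero.
#' @return percent error (vectorized over \code{measured}).
#' @examples
#' percentError(0.284, 0.200)   # 42
#' percentError(0.209, 0.200)   # 4.5
#' @export
percentError <- function(measured, reference) {
  if (any(reference == 0))
    tdsStop("tds_domain_error", "reference must be nonzero")
  100 * abs(measured - reference) / abs(reference)
}

#' Grubbs' test for a single outlier
#'
#' Two-sided single-outlier test: the statistic is the maximum studentized
#' absolute deviation \eqn{G = \max_i |v_i - \bar v| / s} (sample sd); the
#' critical value is
#' \deqn{\frac{n-1}{\sqrt n}\sqrt{\frac{t^2}{n - 2 + t^2}},}
#' with \eqn{t} the upper \eqn{\alpha/(2n)} quantile of the t distribution
#' with \eqn{n - 2} degrees of freedom. The most deviant value is flagged
#' iff \eqn{G} exceeds the critical value. Invariant under shifts and
#' positive rescaling of the data.
#'
#' @param values numeric, n >= 3, not all equal.
#' @param alpha significance level (default 0.05).
#' @return a [GrubbsResult-class].
#' @examples
#' grubbsTest(c(0.202, 0.195, 0.196, 0.241))
#' @export
grubbsTest <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) tdsStop("tds_size_error", "Grubbs' test needs n >= 3")
  s <- sd(values)
  if (s == 0)
    tdsStop("tds_degeneracy_error", "all values are equal: sd is zero")
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  t <- qt(1 - alpha / (2 * n), df = n - 2L)
  crit <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2L + t^2))
  new("GrubbsResult", statistic = G, critical = crit, alpha = alpha,
      outlierIndex = if (G > crit) which.max(dev) else NA_integer_,
      n = as.integer(n))
}
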