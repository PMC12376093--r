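#' Weighted Whittaker smoother
#'
#' Solves the penalized weighted least-squares problem at the heart of
#' airPLS: find \eqn{z} minimizing
#' \deqn{\sum_i w_i (s_i - z_i)^2 + \lambda \sum (\Delta^d z)^2,}
#' i.e. the exact solution of the banded system
#' \eqn{(W + \lambda D'D) z = W s} with \eqn{D} the order-\code{diffOrder}
#' finite-difference matrix. The fidelity term keeps \eqn{z} near the signal
#' where the weights are large; the squared-difference penalty enforces
#' smoothness with strength \eqn{\lambda}.
#'
#' @param signal numeric vector.
#' @param weights nonnegative weights, not all zero (default all 1).
#' @param lambda smoothness penalty, > 0.
#' @param diffOrder order of the difference penalty (default 2; the penalty
#'   then vanishes exactly on straight lines).
#' @return numeric vector \eqn{z}, same length as \code{signal}.
#' @seealso [airPLS()]
#' @export
whittakerWeighted <- function(signal, weights = rep(1, length(signal)),
                              lambda, diffOrder = 2L) {
  n <- length(signal)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    tdsStop("tds_parameter_error", "lambda must be a single positive number")
  if (n < diffOrder + 1L)
    tdsStop("tds_size_error",
            sprintf("signal length %d too short for difference order %d",
                    n, diffOrder))
  if (!all(is.finite(signal)))
    tdsStop("tds_domain_error", "signal must be finite")
  if (any(weights < 0) || !all(is.finite(weights)))
    tdsStop("tds_parameter_error", "weights must be finite and nonnegative")
  if (all(weights == 0))
    tdsStop("tds_degeneracy_error",
            "all weights are zero: the smoothing system is singular")
  D <- Matrix::bandSparse(n - diffOrder, n,
                          k = 0:diffOrder,
                          diagonals = lapply(0:diffOrder, function(k)
                            rep(choose(diffOrder, k) * (-1)^(diffOrder - k),
                                n - diffOrder)))
  A <- Matrix::Diagonal(n, x = weights) + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, weights * signal))
}

#' airPLS baseline estimation
#'
#' Adaptive iteratively reweighted penalized least squares: alternates a
#' weighted Whittaker fit of the baseline \eqn{z} with residual-driven
#' reweighting that removes peak regions from the fit. At iteration
#' \eqn{t}, with residual \eqn{d = s - z} and \eqn{|d|} the L1 norm of its
#' negative part:
#' \itemize{
#'   \item points above the baseline (\eqn{s_i \ge z_i}, i.e. candidate
#'     peaks) get weight 0;
#'   \item points below get weight \eqn{\exp(t |s_i - z_i| / |d|)}, pulling
#'     the baseline up toward the lower envelope of the noise;
#'   \item iteration stops when \eqn{|d| <} \code{terminationRatio}
#'     \eqn{\times |s|} (both L1 norms) or after \code{maxIter} iterations.
#' }
#' Initial weights are all 1. The result is a smooth baseline running under
#' the peaks, suitable for correcting the linear OD across the entire
#' spectral window without manually excluding peak regions.
#'
#' @param signal numeric vector (finite).
#' @param lambda smoothness penalty, > 0. Larger values give stiffer
#'   baselines; raise \eqn{\lambda} for low signal-to-noise data. Default
#'   1e5.
#' @param maxIter iteration cap (default 15).
#' @param terminationRatio stop when the negative-residual norm falls below
#'   this fraction of the signal norm (default 0.001, i.e. 0.1\%).
#' @param diffOrder difference order of the smoothness penalty (default 2).
#' @return a [BaselineResult-class].
#' @examples
#' x <- seq(1500, 1750, by = 0.5)
#' s <- 0.2 * exp(-((x - 1623) / 10)^2) + 1e-3 * (x - 1500)
#' r <- airPLS(s, lambda = 1e5)
#' r
#' @export
airPLS <- function(signal, lambda = 1e5, maxIter = 15L,
                   terminationRatio = 0.001, diffOrder = 2L) {
  if (!all(is.finite(signal)))
    tdsStop("tds_domain_error", "signal must be finite")
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    tdsStop("tds_parameter_error", "lambda must be a single positive number")
  n <- length(signal)
  absS <- sum(abs(signal))
  if (absS == 0) {
    return(new("BaselineResult", baseline = numeric(n), weights = rep(1, n),
               iterations = 1L, converged = TRUE, residualNormRatio = 0,
               lambda = lambda, method = "airpls",
               meta = list(maxIter = maxIter,
                           terminationRatio = terminationRatio)))
  }
  w <- rep(1, n)
  z <- numeric(n); ratio <- NA_real_; converged <- FALSE; t <- 0L
  for (t in seq_len(maxIter)) {
    z <- whittakerWeighted(signal, w, lambda, diffOrder)
    d <- signal - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    ratio <- dssn / absS
    if (dssn == 0 || ratio < terminationRatio) {
      ## dssn == 0: the baseline touches the signal from below everywhere;
      ## reweighting would zero every weight, so this is full convergence
      converged <- TRUE
      break
    }
    wNew <- numeric(n)
    wNew[neg] <- exp(t * abs(d[neg]) / dssn)
    w <- wNew
  }
  ## weights are reported normalized to [0, 1] for diagnostics
  wmax <- max(w)
  new("BaselineResult", baseline = z, weights = if (wmax > 0) w / wmax else w,
      iterations = t, converged = converged, residualNormRatio = ratio,
      lambda = lambda, method = "airpls",
      meta = list(maxIter = maxIter, terminationRatio = terminationRatio,
                  diffOrder = diffOrder))
}

## Savitzky-Golay hat-matrix row: fitted value at position `at` (1-based,
## within the window) of a least-squares polynomial of order p over the
## window offsets
.sgRow <- function(offsets, p, at) {
  X <- outer(offsets, 0:p, `^`)
  H <- X %*% solve(crossprod(X), t(X))
  H[at, ]
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the value at its own position of the least-squares
#' polynomial of order \code{polyOrder} fitted over the centered window of
#' \code{windowPoints} points. The defaults (15-point window, 3rd-order
#' polynomial) are the standard choice for noise filtering of the linear OD
#' before baseline correction. Near the edges, the polynomial of the same
#' order is fitted over the truncated available window rather than padding
#' with fabricated data.
#'
#' @param signal numeric vector, length >= \code{windowPoints}.
#' @param windowPoints odd window length, > \code{polyOrder} (default 15).
#' @param polyOrder polynomial order (default 3).
#' @return smoothed numeric vector, same length.
#' @export
savgolSmooth <- function(signal, windowPoints = 15L, polyOrder = 3L) {
  windowPoints <- as.integer(windowPoints); polyOrder <- as.integer(polyOrder)
  if (windowPoints %% 2L == 0L || windowPoints <= polyOrder)
    tdsStop("tds_parameter_error",
            "windowPoints must be odd and greater than polyOrder")
  n <- length(signal)
  if (n < windowPoints)
    tdsStop("tds_size_error",
            sprintf("signal length %d shorter than window %d", n,
                    windowPoints))
  h <- (windowPoints - 1L) %/% 2L
  out <- numeric(n)
  central <- .sgRow(-h:h, polyOrder, h + 1L)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (hi - lo + 1L == windowPoints) {
      out[i] <- sum(central * signal[lo:hi])
    } else {
      off <- (lo:hi) - i
      ## a truncated window may hold fewer points than polyOrder + 1;
      ## cap the order so the local fit stays determined
      pEff <- min(polyOrder, length(off) - 1L)
      out[i] <- sum(.sgRow(off, pEff, i - lo + 1L) * signal[lo:hi])
    }
  }
  out
}

#' Range-restricted polynomial baseline
#'
#' The manual-comparison pathway: an unweighted least-squares polynomial is
#' fitted to the points inside user-chosen flanking windows only (the
#' regions judged free of peaks), then evaluated over the full axis as the
#' baseline. This is the procedure automated baseline correction is
#' benchmarked against.
#'
#' @param spec a [Spectrum1D-class].
#' @param order polynomial order (e.g. 2 or 3).
#' @param fitRanges list of length-2 numeric wavenumber intervals inside the
#'   spectrum axis, e.g. \code{list(c(1550, 1590), c(1660, 1748))}.
#' @return a [BaselineResult-class] (weights are the 0/1 indicator of fit
#'   points).
#' @seealso [correctBaseline()], [airPLS()]
#' @export
polynomialBaseline <- function(spec, order, fitRanges) {
  if (!length(fitRanges))
    tdsStop("tds_parameter_error", "fitRanges must be nonempty")
  x <- spec@axis; y <- spec@values
  sel <- rep(FALSE, length(x))
  for (rg in fitRanges) {
    if (length(rg) != 2L)
      tdsStop("tds_parameter_error", "each fit range must be c(lo, hi)")
    sel <- sel | (x >= min(rg) & x <= max(rg))
  }
  sel <- sel & spec@mask
  if (sum(sel) < order + 1L)
    tdsStop("tds_degeneracy_error",
            sprintf("fit ranges contain %d point(s); need at least %d for order %d",
                    sum(sel), order + 1L, order))
  x0 <- mean(x[sel])                      # center for conditioning
  X <- outer(x[sel] - x0, 0:order, `^`)
  beta <- qr.coef(qr(X), y[sel])          # QR beats normal equations here
  baseline <- as.numeric(outer(x - x0, 0:order, `^`) %*% beta)
  new("BaselineResult", baseline = baseline, weights = as.numeric(sel),
      iterations = 1L, converged = TRUE, residualNormRatio = NA_real_,
      lambda = NA_real_, method = "polynomial",
      meta = list(order = order, fitRanges = fitRanges))
}

#' Baseline-correct a spectrum
#'
#' Applies the chosen baseline method to a [Spectrum1D-class] and returns
#' the corrected spectrum (\code{spec - baseline}) together with the fit
#' diagnostics. When \code{presmooth = TRUE} a Savitzky-Golay filter is
#' applied to the signal first (smoothing then baseline estimation), as is
#' appropriate for particularly noisy or weak linear OD data; the corrected
#' spectrum is then the smoothed signal minus the baseline.
#'
#' @param spec a [Spectrum1D-class] (typically linear OD).
#' @param method \code{"airpls"} (default) or \code{"polynomial"}.
#' @param lambda,maxIter,terminationRatio airPLS parameters (see
#'   [airPLS()]).
#' @param order,fitRanges polynomial parameters (see
#'   [polynomialBaseline()]).
#' @param presmooth apply Savitzky-Golay smoothing before baseline
#'   estimation (default \code{FALSE}).
#' @param sgWindow,sgOrder Savitzky-Golay window and order (defaults 15, 3).
#' @return a list with elements \code{corrected} ([Spectrum1D-class], with
#'   the processing recorded in \code{specMeta}) and \code{result}
#'   ([BaselineResult-class]).
#' @examples
#' x <- seq(1500, 1750, by = 0.5)
#' s <- spectrum1d(x, 0.2 * exp(-((x - 1623) / 10)^2) + 1e-3 * (x - 1500),
#'                 role = "od")
#' cb <- correctBaseline(s, method = "airpls", lambda = 1e5)
#' cb$result
#' @export
correctBaseline <- function(spec, method = c("airpls", "polynomial"),
                            lambda = 1e5, maxIter = 15L,
                            terminationRatio = 0.001,
                            order = 2L, fitRanges = NULL,
                            presmooth = FALSE, sgWindow = 15L, sgOrder = 3L) {
  method <- match.arg(method)
  y <- spec@values
  if (any(!spec@mask))
    tdsStop("tds_domain_error",
            "baseline correction requires a fully valid (unmasked) spectrum")
  if (presmooth) y <- savgolSmooth(y, sgWindow, sgOrder)
  res <- switch(method,
    airpls = airPLS(y, lambda = lambda, maxIter = maxIter,
                    terminationRatio = terminationRatio),
    polynomial = {
      if (is.null(fitRanges))
        tdsStop("tds_parameter_error",
                "polynomial baseline requires fitRanges")
      polynomialBaseline(spectrum1d(spec@axis, y, role = spec@role),
                         order, fitRanges)
    })
  corrected <- spectrum1d(
    spec@axis, y - res@baseline, role = spec@role, mask = spec@mask,
    meta = c(spec@meta,
             list(baseline_method = method,
                  baseline_presmooth = presmooth,
                  baseline_lambda = if (method == "airpls") lambda else NA,
                  baseline_iterations = res@iterations)))
  list(corrected = corrected, result = res)
}
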