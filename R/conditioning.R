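#' @include AllClasses.R
NULL

#' Smoothness-priors (SPA) detrending
#'
#' Removes the low-frequency trend estimated by the smoothness-priors
#' approach: the trend is \eqn{(I + \lambda^2 D_2^T D_2)^{-1} x} with
#' \eqn{D_2} the second-difference operator, and the detrended signal is
#' the residual \eqn{x - \mathrm{trend}}. Larger \eqn{\lambda} removes
#' only slower trends; as \eqn{\lambda \to 0} the smoother approaches the
#' identity and the residual vanishes. The system matrix is symmetric
#' positive definite, solved by a sparse banded factorization.
#'
#' @param x numeric series (length >= 10).
#' @param lambda smoothing parameter (> 0). The default 60 puts the
#'   smoother's half-power point near 0.62 Hz at 30 Hz sampling: slow
#'   drifts and ramps are removed almost entirely while >= 90% of the
#'   band power at a 1.5 Hz pulse survives.
#' @return Detrended series (near zero mean).
#' @examples
#' x <- seq(0, 1, length.out = 300) + sin(2 * pi * 1.5 * (0:299) / 30)
#' d <- detrendSpa(x)
#' @export
detrendSpa <- function(x, lambda = 60) {
  n <- length(x)
  stopifnot(n >= 10L, lambda > 0)
  d2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                           diagonals = list(rep(1, n - 2L),
                                            rep(-2, n - 2L),
                                            rep(1, n - 2L)))
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(d2)
  trend <- as.numeric(Matrix::solve(A, x))
  x - trend
}

#' Cardiac band-pass filter
#'
#' Fourth-order Butterworth band-pass over 0.5-2.5 Hz (30-150 bpm),
#' applied forward-backward (zero phase). Output is re-centred to zero
#' mean.
#'
#' @param x numeric series.
#' @param frameRate sampling rate (Hz); must exceed 5 Hz.
#' @param band passband (Hz).
#' @param order filter order.
#' @return Filtered, zero-mean series.
#' @export
bandpassCardiac <- function(x, frameRate, band = CARDIAC_BAND, order = 4) {
  if (frameRate <= 2 * band[2L])
    stop("frameRate must exceed ", 2 * band[2L],
         " Hz for the cardiac band-pass")
  if (length(x) < 6 * frameRate)
    warning("series shorter than ~3x the filter settling time; ",
            "edge transients may dominate")
  bf <- signal::butter(order, band / (frameRate / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, x))
  y - mean(y)
}

# Sampling rate implied by a trace's time stamps.
traceRate <- function(t) {
  dt <- median(diff(t))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from t")
  1 / dt
}

# Shared conditioning for every r-PPG technique: per channel, optional
# linear detrend, SPA detrending, and the cardiac band-pass. `detr` keeps
# the (near) zero-mean detrended channel, `restored` adds the channel mean
# back (the form needed by the CHROM/POS running-mean normalizations),
# `bp` is the band-passed channel.
conditionTrace <- function(trace, lambda = 60, linearDetrend = TRUE) {
  stopifnot(is(trace, "RgbTrace"))
  fs <- traceRate(trace@t)
  one <- function(x) {
    mu <- mean(x)
    if (linearDetrend) {
      i <- seq_along(x)
      x <- x - stats::fitted(lm(x ~ i))
    } else x <- x - mu
    d <- detrendSpa(x, lambda)
    list(detr = d, restored = d + mu, bp = bandpassCardiac(d, fs))
  }
  chans <- list(R = one(trace@xR), G = one(trace@xG), B = one(trace@xB))
  list(fs = fs, t = trace@t, chans = chans)
}

# Finalize a 1-D method output into a PulseSignal: band-limit to the
# cardiac band and remove the residual mean.
finishPulse <- function(t, fs, value, method, roiLabel,
                        componentIndex = NA_integer_) {
  v <- bandpassCardiac(value, fs)
  v <- v - mean(v)
  pulseSignal(t, v, method, roiLabel, componentIndex)
}
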