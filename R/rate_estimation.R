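#' @include AllClasses.R
NULL

#' Lomb normalized periodogram
#'
#' Least-squares spectral power estimate valid for arbitrary (including
#' nonuniform) sample times, evaluated on an explicit frequency grid:
#' \deqn{P(f) = \frac{1}{2\sigma^2}\left[
#'   \frac{(\sum (x-\bar x)\cos\omega(t-\tau))^2}{\sum\cos^2\omega(t-\tau)}
#' + \frac{(\sum (x-\bar x)\sin\omega(t-\tau))^2}{\sum\sin^2\omega(t-\tau)}
#' \right]}
#' with the phase constant \eqn{\tau} chosen per frequency so the two
#' terms are orthogonal. A constant window has no spectral content and
#' yields a flat zero spectrum flagged via the `"flat"` attribute.
#'
#' @param x sample values (>= 8 samples).
#' @param t sample times (s), same length.
#' @param grid frequencies to evaluate (Hz), within (0, rate/2].
#' @return data.frame with columns `freq` and `power`; attribute `flat`
#'   is TRUE for a constant window.
#' @examples
#' t <- (0:599) / 30
#' psd <- lombPsd(sin(2 * pi * t), t, seq(0.5, 2.5, by = 0.01))
#' psd$freq[which.max(psd$power)] # 1 Hz
#' @export
lombPsd <- function(x, t, grid) {
  stopifnot(length(x) == length(t), length(x) >= 8L, all(grid > 0))
  xm <- x - mean(x)
  s2 <- var(x)
  if (!is.finite(s2) || s2 <= 0) {
    out <- data.frame(freq = grid, power = rep(0, length(grid)))
    attr(out, "flat") <- TRUE
    return(out)
  }
  omega <- 2 * pi * grid
  wt <- outer(t, omega)                      # N x F
  tau <- atan2(colSums(sin(2 * wt)), colSums(cos(2 * wt))) / (2 * omega)
  arg <- wt - rep(omega * tau, each = length(t))
  ca <- cos(arg); sa <- sin(arg)
  p <- (colSums(xm * ca)^2 / colSums(ca * ca) +
        colSums(xm * sa)^2 / colSums(sa * sa)) / (2 * s2)
  out <- data.frame(freq = grid, power = p)
  attr(out, "flat") <- FALSE
  out
}

#' Rate from a windowed power spectrum
#'
#' Converts the frequency of the highest in-band PSD peak to a rate in
#' events per minute: rate = 60 x argmax-frequency. A flat (all-zero)
#' in-band spectrum yields NA.
#'
#' @param psd data.frame (freq, power) from [lombPsd()].
#' @param band (f_lo, f_hi) search band in Hz.
#' @return Rate (bpm or breaths/min), or NA for a flat window.
#' @export
rateFromWindow <- function(psd, band) {
  sel <- psd$freq >= band[1L] & psd$freq <= band[2L]
  if (!any(sel)) stop("band lies outside the evaluated grid")
  p <- psd$power[sel]
  if (isTRUE(attr(psd, "flat")) || all(p <= 0)) return(NA_real_)
  60 * psd$freq[sel][which.max(p)]
}

#' Sliding-window rate estimation
#'
#' Applies the Lomb periodogram in a moving window (20 s by default)
#' sliding in 1 s steps over a pulse or displacement signal, taking
#' 60 x the frequency of the highest in-band peak of each window. A
#' signal of duration T yields floor((T - window)/step) + 1 estimates,
#' timestamped at their window end.
#'
#' @param x a [PulseSignal-class], [DisplacementTrace-class], or numeric
#'   vector.
#' @param cfg a [SpectralConfig-class]; its band selects cardiac
#'   (0.5-2.5 Hz) or respiratory (0.05-2 Hz) analysis.
#' @param t sample times, required when `x` is a bare numeric vector.
#' @param source provenance label stored on the result.
#' @return A [RateSeries-class].
#' @export
slidingRates <- function(x, cfg = spectralConfig(), t = NULL,
                         source = NULL) {
  if (is(x, "PulseSignal")) {
    if (is.null(source))
      source <- paste0(x@method, ":", x@roiLabel)
    t <- x@t; v <- x@value
  } else if (is(x, "DisplacementTrace")) {
    if (is.null(source)) source <- "flow:Torso"
    t <- x@t; v <- x@sy
  } else {
    v <- as.numeric(x)
    if (is.null(t)) stop("t is required for a bare numeric signal")
    if (is.null(source)) source <- "unknown"
  }
  stopifnot(is(cfg, "SpectralConfig"))
  dt <- median(diff(t))
  dur <- length(v) * dt
  if (dur < cfg@windowS - 1e-9)
    stop("signal duration (", round(dur, 2), " s) shorter than the ",
         cfg@windowS, " s analysis window")
  # guard the count against floating-point duration (e.g. 1800/30 s)
  nWin <- floor((dur - cfg@windowS) / cfg@stepS + 1e-9) + 1L
  grid <- seq(cfg@band[1L], cfg@band[2L], by = cfg@gridHz)
  t0 <- t[1L]
  rate <- numeric(nWin)
  tOut <- numeric(nWin)
  uniform <- max(abs(diff(t) - dt)) < 1e-9 * dt
  if (uniform) {
    # every window shares one relative time grid, and the Lomb
    # periodogram is invariant to a time-origin shift: precompute the
    # per-frequency basis once and reuse it for all window positions
    winLen <- round(cfg@windowS / dt)
    tRel <- (seq_len(winLen) - 1) * dt
    omega <- 2 * pi * grid
    wt <- outer(tRel, omega)
    tau <- atan2(colSums(sin(2 * wt)), colSums(cos(2 * wt))) /
      (2 * omega)
    arg <- wt - rep(omega * tau, each = winLen)
    ca <- cos(arg); sa <- sin(arg)
    cc <- colSums(ca * ca); ss <- colSums(sa * sa)
    for (k in seq_len(nWin)) {
      start <- min(round((k - 1) * cfg@stepS / dt) + 1L,
                   length(v) - winLen + 1L)
      idx <- start:(start + winLen - 1L)
      xw <- v[idx]
      s2 <- var(xw)
      rate[k] <- if (!is.finite(s2) || s2 <= 0) NA_real_ else {
        p <- (as.vector(crossprod(ca, xw - mean(xw)))^2 / cc +
              as.vector(crossprod(sa, xw - mean(xw)))^2 / ss) / (2 * s2)
        if (all(p <= 0)) NA_real_ else 60 * grid[which.max(p)]
      }
      tOut[k] <- t0 + (k - 1) * cfg@stepS + cfg@windowS
    }
  } else {
    for (k in seq_len(nWin)) {
      wStart <- t0 + (k - 1) * cfg@stepS
      idx <- which(t >= wStart - dt / 2 &
                     t < wStart + cfg@windowS - dt / 2)
      psd <- lombPsd(v[idx], t[idx], grid)
      rate[k] <- rateFromWindow(psd, cfg@band)
      tOut[k] <- wStart + cfg@windowS
    }
  }
  rateSeries(tOut, rate, source = source)
}

#' Replace rate outliers by their nearest valid neighbours
#'
#' Computes Tukey fences Q1 - 1.5 IQR and Q3 + 1.5 IQR over the whole
#' series (quartiles by linear interpolation between order statistics)
#' and replaces every value outside them -- and every missing value --
#' with the temporally nearest non-outlier value, earlier samples winning
#' ties. Replaced samples are flagged.
#'
#' Replacing a value can tighten the fences enough to expose further
#' outliers, so the screen is repeated until no value moves; this makes
#' the operation idempotent by construction (a second call changes
#' nothing). Values never flagged keep their original value. The first
#' pass is exactly the single screen described above.
#'
#' @param series a [RateSeries-class] with at least 4 samples.
#' @return A [RateSeries-class] with outliers replaced and flagged.
#' @examples
#' rs <- rateSeries(1:5, c(70, 71, 72, 73, 200))
#' rateValues(replaceOutliers(rs)) # 200 -> 73
#' @export
replaceOutliers <- function(series) {
  stopifnot(is(series, "RateSeries"), length(series@rate) >= 4L)
  r <- series@rate
  flagged <- rep(FALSE, length(r))
  for (pass in seq_len(25L)) {
    q <- quantile(r, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                  type = 7)
    iqr <- q[2L] - q[1L]
    bad <- is.na(r) | r < q[1L] - 1.5 * iqr | r > q[2L] + 1.5 * iqr
    if (!any(bad)) break
    flagged <- flagged | bad
    good <- which(!flagged)
    if (length(good) == 0L)
      stop("no non-outlier values to substitute from")
    for (i in which(bad)) {
      d <- abs(series@t[good] - series@t[i])
      r[i] <- r[good[which.min(d)]]  # which.min: earliest wins ties
    }
  }
  rateSeries(series@t, r, outlier = flagged, source = series@source)
}

#' Fuse the three facial ROI rate series by averaging
#'
#' Element-wise arithmetic mean of the LCheek, FHead and RCheek series
#' (each already outlier-replaced):
#' \eqn{HR_{mean} = (HR_{LCheek} + HR_{FHead} + HR_{RCheek}) / 3}.
#'
#' @param hrL,hrF,hrR [RateSeries-class] objects on identical time bases.
#' @return A fused [RateSeries-class] (source `"multi"`); a sample is
#'   flagged when it was flagged in any input.
#' @export
fuseMultiRoi <- function(hrL, hrF, hrR) {
  if (!isTRUE(all.equal(hrL@t, hrF@t)) ||
      !isTRUE(all.equal(hrL@t, hrR@t)))
    stop("rate series must share one time base")
  rateSeries(hrL@t, (hrL@rate + hrF@rate + hrR@rate) / 3,
             outlier = hrL@outlier | hrF@outlier | hrR@outlier,
             source = "multi")
}

#' Spectral signal-to-noise ratio of a pulse signal
#'
#' The ratio, in dB, of periodogram energy inside a template around the
#' pulse fundamental and its first harmonic to the energy elsewhere in
#' 0.5-4 Hz: template = (f0 +/- guard) u (2 f0 +/- guard). The
#' magnitude-squared FFT periodogram is used; the fundamental defaults to
#' the signal's own highest in-band peak. A pure in-template tone gives
#' the +100 dB cap.
#'
#' @param x a [PulseSignal-class] or numeric vector.
#' @param frameRate sampling rate (Hz); inferred from a PulseSignal.
#' @param fundamental pulse frequency (Hz); NULL = signal's in-band peak.
#' @param guard template half-width (Hz).
#' @param range spectral range considered (Hz).
#' @return SNR in dB (capped at 100).
#' @export
snrDb <- function(x, frameRate = NULL, fundamental = NULL, guard = 0.1,
                  range = c(0.5, 4)) {
  if (is(x, "PulseSignal")) {
    if (is.null(frameRate)) frameRate <- 1 / median(diff(x@t))
    x <- x@value
  }
  stopifnot(!is.null(frameRate))
  n <- length(x)
  xm <- x - mean(x)
  pxx <- Mod(fft(xm))^2
  freq <- (seq_len(n) - 1L) * frameRate / n
  keep <- freq >= range[1L] & freq <= min(range[2L], frameRate / 2)
  f <- freq[keep]; p <- pxx[keep]
  if (is.null(fundamental)) {
    inBand <- f >= CARDIAC_BAND[1L] & f <= CARDIAC_BAND[2L]
    if (!any(inBand) || all(p[inBand] <= 0)) return(-Inf)
    fundamental <- f[inBand][which.max(p[inBand])]
  }
  template <- abs(f - fundamental) <= guard |
    abs(f - 2 * fundamental) <= guard
  eIn <- sum(p[template]); eOut <- sum(p[!template])
  if (eOut <= 0) return(100)
  min(10 * log10(eIn / eOut), 100)
}

#' Select the best ROI's pulse signal by SNR
#'
#' Among candidate pulse signals of one technique (one per facial ROI),
#' returns the one with the highest spectral SNR; exact ties resolve in
#' the priority order RCheek, FHead, LCheek. The winning SNR is attached
#' as attribute `"snr"`.
#'
#' @param candidates list of [PulseSignal-class] objects (>= 1).
#' @param ... passed on to [snrDb()].
#' @return The selected [PulseSignal-class].
#' @export
selectBySnr <- function(candidates, ...) {
  stopifnot(length(candidates) >= 1L)
  priority <- c("RCheek", "FHead", "LCheek")
  rank <- vapply(candidates, function(p) {
    r <- match(p@roiLabel, priority)
    if (is.na(r)) length(priority) + 1L else r
  }, integer(1L))
  ord <- order(rank)
  candidates <- candidates[ord]
  snr <- vapply(candidates, snrDb, numeric(1L), ...)
  best <- which.max(snr)   # first max in priority order
  out <- candidates[[best]]
  attr(out, "snr") <- snr[best]
  out
}
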