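#' @include AllClasses.R conditioning.R wavelet.R jade.R
NULL

#' Extract the per-frame RGB trace of a ROI
#'
#' Spatially averages each channel over the ROI pixels, frame by frame,
#' giving the raw three-dimensional r-PPG observation for that region.
#'
#' @param seq an RGB [FrameSequence-class].
#' @param roi one-row ROI data.frame (see [getRoi()]).
#' @return An [RgbTrace-class].
#' @export
extractRgbTrace <- function(seq, roi) {
  stopifnot(is(seq, "FrameSequence"), seq@colorMode == "rgb")
  rows <- roiRows(roi); cols <- roiCols(roi)
  d <- dim(seq@frames)
  if (max(rows) > d[1L] || max(cols) > d[2L] || min(rows) < 1L ||
      min(cols) < 1L)
    stop("roi lies outside the frames")
  n <- d[4L]
  sub <- seq@frames[rows, cols, , , drop = FALSE]
  means <- apply(sub, c(3L, 4L), mean)
  t <- (seq_len(n) - 1) / seq@frameRate
  rgbTrace(t, means[1L, ], means[2L, ], means[3L, ],
           roiLabel = roi$label)
}

#' Green-channel pulse extraction
#'
#' The green channel carries the strongest blood-volume-pulse modulation;
#' this baseline technique simply passes the conditioned (detrended,
#' band-passed) green channel through as the candidate pulse signal.
#'
#' @param trace an [RgbTrace-class].
#' @param lambda SPA detrending parameter.
#' @return A [PulseSignal-class] (method `"Green"`).
#' @export
methodGreen <- function(trace, lambda = 60) {
  cond <- conditionTrace(trace, lambda)
  finishPulse(cond$t, cond$fs, cond$chans$G$bp, "Green", trace@roiLabel)
}

#' MODWT multiresolution pulse extraction
#'
#' Decomposes the conditioned green channel with a 4-level maximal-overlap
#' discrete wavelet transform (symlet-4) and reconstructs the sum of the
#' components whose dyadic band \eqn{[f_s/2^{j+1}, f_s/2^j]} intersects
#' the cardiac band 0.5-2.5 Hz: details 3 and 4 at 30 fps, plus the
#' final smooth, whose band \eqn{[0, f_s/2^J]} reaches up to 0.94 Hz and
#' therefore still carries heart rates below ~56 bpm. The closing
#' band-pass removes the smooth's sub-cardiac content, so fast noise and
#' slow drifts are suppressed while the whole 30-150 bpm range stays
#' recoverable.
#'
#' @param trace an [RgbTrace-class].
#' @param lambda SPA detrending parameter.
#' @param nLevels decomposition depth.
#' @return A [PulseSignal-class] (method `"MODW"`).
#' @export
methodModwt <- function(trace, lambda = 60, nLevels = 4) {
  cond <- conditionTrace(trace, lambda)
  fs <- cond$fs
  mra <- modwtMra(cond$chans$G$detr, nLevels = nLevels)
  keep <- vapply(seq_len(nLevels), function(j) {
    lo <- fs / 2^(j + 1); hi <- fs / 2^j
    lo < CARDIAC_BAND[2L] && hi > CARDIAC_BAND[1L]
  }, logical(1L))
  if (!any(keep))
    stop("no detail level intersects the cardiac band at ", fs, " fps")
  value <- Reduce(`+`, mra$details[keep])
  # the final smooth holds [0, fs/2^J]: at 30 fps that is 0-0.94 Hz,
  # which still overlaps the low end of the cardiac band (30-56 bpm),
  # so it is kept; the closing band-pass removes its sub-cardiac part
  if (fs / 2^nLevels > CARDIAC_BAND[1L])
    value <- value + mra$smooth
  finishPulse(cond$t, fs, value, "MODW", trace@roiLabel)
}

hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

#' CHROM chrominance pulse extraction
#'
#' Projects the temporally normalized RGB channels onto the chrominance
#' axes X_s = 3R_n - 2G_n and Y_s = 1.5R_n + G_n - 1.5B_n and combines
#' them as S = X_s - (sigma(X_s)/sigma(Y_s)) Y_s, cancelling the
#' intensity/specular component that is common to all channels. The
#' projection is computed on Hann-windowed segments with 50% overlap-add
#' (segment length 1.6 s); each channel is normalized by its segment mean
#' (x / mean - 1), making the method invariant to channel scaling.
#'
#' @param trace an [RgbTrace-class].
#' @param lambda SPA detrending parameter.
#' @param segmentS segment length (s).
#' @return A [PulseSignal-class] (method `"CHROM"`).
#' @export
methodChrom <- function(trace, lambda = 60, segmentS = 1.6) {
  cond <- conditionTrace(trace, lambda)
  fs <- cond$fs
  n <- length(cond$t)
  L <- min(n, max(4L, round(segmentS * fs)))
  hop <- max(1L, floor(L / 2))
  starts <- unique(c(seq(1L, n - L + 1L, by = hop), n - L + 1L))
  xr <- cond$chans$R$restored
  xg <- cond$chans$G$restored
  xb <- cond$chans$B$restored
  win <- hannWindow(L)
  acc <- numeric(n); wsum <- numeric(n)
  normSeg <- function(x) {
    mu <- mean(x)
    if (abs(mu) < .Machine$double.eps) numeric(length(x)) else x / mu - 1
  }
  for (s0 in starts) {
    idx <- s0:(s0 + L - 1L)
    Rn <- normSeg(xr[idx]); Gn <- normSeg(xg[idx]); Bn <- normSeg(xb[idx])
    Xs <- 3 * Rn - 2 * Gn
    Ys <- 1.5 * Rn + Gn - 1.5 * Bn
    sdY <- sd(Ys)
    alpha <- if (sdY > 0) sd(Xs) / sdY else 0
    S <- Xs - alpha * Ys
    S <- S - mean(S)
    acc[idx] <- acc[idx] + S * win
    wsum[idx] <- wsum[idx] + win
  }
  value <- acc / pmax(wsum, 1e-3)
  finishPulse(cond$t, fs, value, "CHROM", trace@roiLabel)
}

#' POS (plane-orthogonal-to-skin) pulse extraction
#'
#' Within a sliding window of 1.6 s the channels are normalized by their
#' window means and projected onto the two axes orthogonal to the skin
#' tone, S1 = G_n - B_n and S2 = G_n + B_n - 2R_n; the window's pulse
#' contribution h = S1 + (sigma(S1)/sigma(S2)) S2 is mean-removed and
#' overlap-added. Intensity flicker common to all channels lies along the
#' normalized intensity direction, orthogonal to both axes, and is
#' suppressed.
#'
#' @param trace an [RgbTrace-class].
#' @param lambda SPA detrending parameter.
#' @param windowS sliding window length (s).
#' @return A [PulseSignal-class] (method `"POS"`).
#' @export
methodPos <- function(trace, lambda = 60, windowS = 1.6) {
  cond <- conditionTrace(trace, lambda)
  fs <- cond$fs
  n <- length(cond$t)
  L <- min(n, max(4L, round(windowS * fs)))
  xr <- cond$chans$R$restored
  xg <- cond$chans$G$restored
  xb <- cond$chans$B$restored
  h <- numeric(n)
  normWin <- function(x) {
    mu <- mean(x)
    if (abs(mu) < .Machine$double.eps) rep(1, length(x)) else x / mu
  }
  for (nEnd in L:n) {
    idx <- (nEnd - L + 1L):nEnd
    Rn <- normWin(xr[idx]); Gn <- normWin(xg[idx]); Bn <- normWin(xb[idx])
    S1 <- Gn - Bn
    S2 <- Gn + Bn - 2 * Rn
    sd2 <- sd(S2)
    hw <- if (sd2 > 0) S1 + (sd(S1) / sd2) * S2 else S1
    h[idx] <- h[idx] + (hw - mean(hw))
  }
  finishPulse(cond$t, fs, h, "POS", trace@roiLabel)
}

#' Blind-source-separation pulse extraction (ICA / PCA)
#'
#' Unmixes the three conditioned channels into three candidate sources --
#' by JADE joint-diagonalization ICA or by the eigendecomposition of the
#' channel covariance (PCA) -- and, because blind separation returns
#' components in arbitrary order, selects the component whose normalized
#' periodogram contains the highest single peak inside the cardiac band.
#' Rank-deficient input (e.g. identical channels) falls back to the green
#' channel with a warning.
#'
#' @param trace an [RgbTrace-class].
#' @param kind `"ICA"` or `"PCA"`.
#' @param lambda SPA detrending parameter.
#' @return A [PulseSignal-class] with `componentIndex` recording the
#'   selected component.
#' @export
methodBss <- function(trace, kind = c("ICA", "PCA"), lambda = 60) {
  kind <- match.arg(kind)
  cond <- conditionTrace(trace, lambda)
  fs <- cond$fs
  X <- rbind(cond$chans$R$bp, cond$chans$G$bp, cond$chans$B$bp)
  C <- tcrossprod(X - rowMeans(X)) / ncol(X)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[1L] <= 0 || eg$values[3L] / eg$values[1L] < 1e-10) {
    warning("rank-deficient channels; falling back to the green channel")
    ps <- methodGreen(trace, lambda)
    return(pulseSignal(ps@t, ps@value, kind, trace@roiLabel, NA_integer_))
  }
  S <- if (kind == "ICA") jadeIca(X)$S
       else t(eg$vectors) %*% (X - rowMeans(X))
  grid <- seq(CARDIAC_BAND[1L], CARDIAC_BAND[2L], by = 0.01)
  peak <- vapply(seq_len(nrow(S)), function(i) {
    psd <- lombPsd(S[i, ], cond$t, grid)
    max(psd$power)
  }, numeric(1L))
  sel <- which.max(peak)
  finishPulse(cond$t, fs, S[sel, ], kind, trace@roiLabel,
              componentIndex = sel)
}
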