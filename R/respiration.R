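#' @include AllClasses.R video_io.R roi_detect.R
NULL

#' Horn-Schunck dense optical flow between two frames
#'
#' Estimates the per-pixel velocity field (vx, vy) between two greyscale
#' frames by minimizing the Horn-Schunck energy: the brightness-constancy
#' residual \eqn{I_x v_x + I_y v_y + I_t} plus an
#' \eqn{\alpha^2}-weighted smoothness penalty on the flow field. Spatial
#' and temporal derivatives use the classic 4-point forward-difference
#' stencils averaged over the two frames; the solution is found by the
#' Jacobi-style fixed-point iteration with the 1/6-1/12 neighbourhood
#' average, run until the update falls below `tol` or `nIter` sweeps.
#'
#' @param iPrev,iNext same-shape numeric matrices (greyscale frames).
#' @param alpha smoothness weight (> 0); the classic default 1.
#' @param nIter maximum iterations.
#' @param tol early-stop threshold on the maximum absolute flow update
#'   (1e-3 px/frame leaves the ROI-mean velocity unchanged at far lower
#'   cost than running to full convergence).
#' @return A list with matrices `vx` and `vy` (px/frame), same shape as
#'   the input frames.
#' @examples
#' a <- outer(1:20, 1:20, function(y, x) x + y)
#' f <- hornSchunck(a, a)
#' max(abs(f$vy)) # zero temporal derivative -> zero flow
#' @export
hornSchunck <- function(iPrev, iNext, alpha = 1, nIter = 100, tol = 1e-3) {
  if (!all(dim(iPrev) == dim(iNext)))
    stop("frames must have the same shape")
  stopifnot(alpha > 0, nIter >= 1)
  hs_flow_cpp(iPrev, iNext, alpha, as.integer(nIter), tol)
}

#' Mean vertical velocity over a ROI
#'
#' Arithmetic mean of the vertical flow component over the pixels of one
#' region of interest: the single per-frame value that, integrated over
#' time, yields the chest displacement signal.
#'
#' @param flow list with `vx`, `vy` matrices from [hornSchunck()].
#' @param roi one-row ROI data.frame (see [getRoi()]), in the coordinate
#'   frame of `flow` unless `origin` says otherwise.
#' @param origin 0-based (x, y) of the flow field's top-left pixel in full
#'   frame coordinates (non-zero when flow was computed on a crop).
#' @return Mean vy (px/frame), a single number.
#' @export
meanVerticalVelocity <- function(flow, roi, origin = c(0L, 0L)) {
  rows <- roiRows(roi) - origin[2L]
  cols <- roiCols(roi) - origin[1L]
  if (min(rows) < 1L || min(cols) < 1L || max(rows) > nrow(flow$vy) ||
      max(cols) > ncol(flow$vy))
    stop("roi lies outside the flow field")
  mean(flow$vy[rows, cols])
}

#' Integrate a velocity series into displacement
#'
#' Cumulative trapezoidal integration with dt = 1/frameRate and s[1] = 0:
#' turns the per-frame mean vertical velocity into the linear chest
#' displacement s_y.
#'
#' @param vyMean velocity series (px/frame).
#' @param frameRate sampling rate (Hz).
#' @return Displacement series, same length as `vyMean`.
#' @export
integrateVelocity <- function(vyMean, frameRate) {
  stopifnot(all(is.finite(vyMean)), frameRate > 0)
  n <- length(vyMean)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((vyMean[-1L] + vyMean[-n]) / 2)) / frameRate
}

#' Respiratory band-pass filter
#'
#' First-order Butterworth band-pass over 0.05-2 Hz (3-120 breaths/min),
#' applied forward-backward (zero phase) so the apnea endpoint used for
#' synchronization is not displaced in time.
#'
#' @param x displacement series.
#' @param frameRate sampling rate (Hz); must exceed 4 Hz so the 2 Hz upper
#'   cutoff is realizable.
#' @param band passband (Hz).
#' @return Filtered series.
#' @export
bandpassRespiratory <- function(x, frameRate, band = RESPIRATORY_BAND) {
  if (frameRate <= 2 * band[2L])
    stop("frameRate must exceed ", 2 * band[2L],
         " Hz for the respiratory band-pass")
  bf <- signal::butter(1, band / (frameRate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Extract the respiratory displacement signal from a video
#'
#' End-to-end respiration stage: greyscale conversion, Horn-Schunck
#' optical flow between consecutive frames over the torso ROI (computed on
#' a crop extending `margin` px beyond the ROI; the smoothness coupling
#' farther away has negligible influence on interior velocities), spatial
#' averaging of vy, trapezoidal integration, and first-order Butterworth
#' band-pass over the respiratory band. The resulting trace has one sample
#' per frame pair, timestamped at the later frame.
#'
#' @param seq a [FrameSequence-class] (RGB or greyscale).
#' @param roi one-row torso ROI data.frame, e.g.
#'   `getRoi(roiset, "Torso")`.
#' @param alpha,nIter,tol Horn-Schunck parameters (see [hornSchunck()]).
#' @param margin crop margin around the ROI (px).
#' @param bandpass apply the respiratory band-pass (default TRUE).
#' @return A [DisplacementTrace-class].
#' @export
extractRespiration <- function(seq, roi, alpha = 1, nIter = 100,
                               tol = 1e-3, margin = 12, bandpass = TRUE) {
  stopifnot(is(seq, "FrameSequence"))
  fs <- frameRate(seq)
  n <- nFrames(seq)
  if (n < 2L) stop("need at least two frames")
  H <- dim(seq@frames)[1L]; W <- dim(seq@frames)[2L]
  r0 <- max(1L, roi$y0 + 1L - margin)
  r1 <- min(H, roi$y0 + roi$height + margin)
  c0 <- max(1L, roi$x0 + 1L - margin)
  c1 <- min(W, roi$x0 + roi$width + margin)
  origin <- c(c0 - 1L, r0 - 1L)
  # greyscale-convert only the torso crop, frame by frame: the rest of
  # the frame never feeds the flow, and this keeps memory flat
  greyCrop <- if (seq@colorMode == "grey")
    function(f) seq@frames[r0:r1, c0:c1, 1L, f]
  else
    function(f)
      0.299 * seq@frames[r0:r1, c0:c1, 1L, f] +
      0.587 * seq@frames[r0:r1, c0:c1, 2L, f] +
      0.114 * seq@frames[r0:r1, c0:c1, 3L, f]
  vy <- numeric(n - 1L)
  prev <- greyCrop(1L)
  for (f in 2:n) {
    cur <- greyCrop(f)
    flow <- hornSchunck(prev, cur, alpha = alpha, nIter = nIter, tol = tol)
    vy[f - 1L] <- meanVerticalVelocity(flow, roi, origin = origin)
    prev <- cur
  }
  sRaw <- integrateVelocity(vy, fs)
  sy <- if (bandpass) bandpassRespiratory(sRaw, fs) else sRaw
  displacementTrace(seq_len(n - 1L) / fs, sy, vy)
}
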