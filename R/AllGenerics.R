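#' @include AllClasses.R
NULL

#' Number of frames in a sequence
#' @param x a [FrameSequence-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameSequence", function(x) dim(x@frames)[4L])

#' Frame rate accessor
#' @param x a [FrameSequence-class].
#' @return frames per second (Hz).
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname frameRate
#' @export
setMethod("frameRate", "FrameSequence", function(x) x@frameRate)

#' Frame size accessor
#' @param x a [FrameSequence-class].
#' @return integer (width, height) in pixels.
#' @export
setGeneric("frameSize", function(x) standardGeneric("frameSize"))

#' @rdname frameSize
#' @export
setMethod("frameSize", "FrameSequence",
          function(x) c(width = dim(x@frames)[2L],
                        height = dim(x@frames)[1L]))

#' Extract one frame
#' @param x a [FrameSequence-class].
#' @param i frame index (1-based).
#' @return an H x W x C numeric array.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setMethod("getFrame", "FrameSequence", function(x, i) {
  stopifnot(i >= 1L, i <= nFrames(x))
  x@frames[, , , i, drop = FALSE][, , , 1L]
})

#' Look up a single ROI by label
#' @param x a [RoiSet-class].
#' @param label one of LCheek, FHead, RCheek, Torso.
#' @return a one-row data.frame (label, x0, y0, width, height).
#' @export
setGeneric("getRoi", function(x, label) standardGeneric("getRoi"))

#' @rdname getRoi
#' @export
setMethod("getRoi", "RoiSet", function(x, label) {
  r <- x@rois[x@rois$label == label, , drop = FALSE]
  if (nrow(r) != 1L) stop("no ROI labelled '", label, "'")
  r
})

#' Sample times accessor
#' @param x a trace, signal or rate-series object.
#' @return numeric vector of times (s).
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "RgbTrace", function(x) x@t)
#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "DisplacementTrace", function(x) x@t)
#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "PulseSignal", function(x) x@t)
#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "RateSeries", function(x) x@t)

#' Rate values accessor
#' @param x a [RateSeries-class].
#' @return numeric vector of rates.
#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))

#' @rdname rateValues
#' @export
setMethod("rateValues", "RateSeries", function(x) x@rate)

#' Outlier flags accessor
#' @param x a [RateSeries-class].
#' @return logical vector, TRUE where a value was replaced.
#' @export
setGeneric("outlierFlags", function(x) standardGeneric("outlierFlags"))

#' @rdname outlierFlags
#' @export
setMethod("outlierFlags", "RateSeries", function(x) x@outlier)

#' Pulse values accessor
#' @param x a [PulseSignal-class].
#' @return numeric vector.
#' @export
setGeneric("pulseValues", function(x) standardGeneric("pulseValues"))

#' @rdname pulseValues
#' @export
setMethod("pulseValues", "PulseSignal", function(x) x@value)

#' Displacement values accessor
#' @param x a [DisplacementTrace-class].
#' @return numeric vector (the s_y series).
#' @export
setGeneric("displacement", function(x) standardGeneric("displacement"))

#' @rdname displacement
#' @export
setMethod("displacement", "DisplacementTrace", function(x) x@sy)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames, %dx%d px, %s, %.6g fps (%.1f s)\n",
              d[4L], d[2L], d[1L], object@colorMode, object@frameRate,
              d[4L] / object@frameRate))
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet (%s):\n", object@source))
  print(object@rois, row.names = FALSE)
})

setMethod("show", "RgbTrace", function(object) {
  cat(sprintf("RgbTrace [%s]: %d samples, %.1f s\n", object@roiLabel,
              length(object@t),
              if (length(object@t)) diff(range(object@t)) else 0))
})

setMethod("show", "DisplacementTrace", function(object) {
  cat(sprintf("DisplacementTrace: %d samples, %.1f s, sd(s_y) = %.4g\n",
              length(object@t),
              if (length(object@t)) diff(range(object@t)) else 0,
              sd(object@sy)))
})

setMethod("show", "PulseSignal", function(object) {
  cat(sprintf("PulseSignal [%s @ %s]%s: %d samples\n", object@method,
              object@roiLabel,
              if (is.na(object@componentIndex)) "" else
                sprintf(" (component %d)", object@componentIndex),
              length(object@t)))
})

setMethod("show", "RateSeries", function(object) {
  cat(sprintf(
    "RateSeries [%s]: %d estimates, median %.1f, %d replaced outlier(s)\n",
    object@source, length(object@t), median(object@rate, na.rm = TRUE),
    sum(object@outlier)))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport (n = %d):\n", object@n))
  cat(sprintf("  MOD +/- LOA : %.3f +/- %.3f\n", object@mod,
              object@loaHalfWidth))
  cat(sprintf("  MAE         : %.3f\n", object@mae))
  cat(sprintf("  RMSE        : %.3f\n", object@rmse))
  cat(sprintf("  R^2         : %s\n",
              if (is.na(object@r2)) "NA" else sprintf("%.4f", object@r2)))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(paste0(
    "SceneConfig: %gx%g px @ %g fps, %g s (apnea %g s)\n",
    "  HR %g bpm, fR %g breaths/min, pulse amp (%.3g, %.3g, %.3g)\n",
    "  resp amp %g px, trend %g counts / %g s, noise sd %g, seed %d\n"),
    object@frameSize[1L], object@frameSize[2L], object@frameRate,
    object@duration, object@apneaDuration, object@hrTrue, object@frTrue,
    object@pulseAmpRgb[1L], object@pulseAmpRgb[2L], object@pulseAmpRgb[3L],
    object@respAmp, object@trendAmp, object@trendPeriod, object@noiseSd,
    object@seed))
})

setMethod("show", "SpectralConfig", function(object) {
  cat(sprintf(
    "SpectralConfig: %g s window / %g s step, grid %g Hz, band %g-%g Hz\n",
    object@windowS, object@stepS, object@gridHz, object@band[1L],
    object@band[2L]))
})
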