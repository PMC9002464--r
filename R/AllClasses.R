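#' @import methods
#' @importFrom stats approx coef cor fft lm median quantile rnorm sd var
#' @importFrom utils read.csv write.csv
NULL

ROI_LABELS <- c("LCheek", "FHead", "RCheek", "Torso")
FACE_ROI_LABELS <- c("LCheek", "FHead", "RCheek")
RPPG_METHODS <- c("Green", "MODW", "CHROM", "POS", "ICA", "PCA")

#' FrameSequence: an ordered stack of video frames
#'
#' Holds the raw observation \eqn{I(x, y, f)}: an ordered set of equally
#' sized frames with a fixed frame rate. Pixel coordinates follow the image
#' convention: origin at the top-left corner, x growing rightward (columns),
#' y growing downward (rows). RGB frames are stored as an H x W x 3 x N
#' array of intensity counts in [0, 255]; greyscale frames as H x W x 1 x N
#' at floating precision (no re-quantization after the RGB-to-grey map).
#'
#' @slot frames numeric array, dimensions H x W x C x N (C = 3 for RGB,
#'   C = 1 for greyscale).
#' @slot frameRate frames per second (Hz).
#' @slot colorMode `"rgb"` or `"grey"`.
#' @export
setClass("FrameSequence",
  representation(frames = "array", frameRate = "numeric",
                 colorMode = "character"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@frames)
    if (length(d) != 4L)
      msg <- c(msg, "frames must be an H x W x C x N array")
    else {
      if (object@colorMode == "rgb" && d[3L] != 3L)
        msg <- c(msg, "rgb frames must have 3 channels")
      if (object@colorMode == "grey" && d[3L] != 1L)
        msg <- c(msg, "grey frames must have 1 channel")
      if (d[4L] < 1L) msg <- c(msg, "need at least one frame")
    }
    if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
        object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (!object@colorMode %in% c("rgb", "grey"))
      msg <- c(msg, "colorMode must be 'rgb' or 'grey'")
    if (anyNA(object@frames))
      msg <- c(msg, "frames must not contain missing values")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a FrameSequence
#'
#' @param frames H x W x C x N array (or H x W x N, promoted to C = 1).
#' @param frameRate frames per second (Hz).
#' @param colorMode `"rgb"` or `"grey"`; inferred from the channel count
#'   when missing.
#' @return A [FrameSequence-class] object.
#' @export
frameSequence <- function(frames, frameRate, colorMode = NULL) {
  if (length(dim(frames)) == 3L)
    dim(frames) <- c(dim(frames)[1:2], 1L, dim(frames)[3L])
  if (is.null(colorMode))
    colorMode <- if (dim(frames)[3L] == 3L) "rgb" else "grey"
  new("FrameSequence", frames = frames, frameRate = as.numeric(frameRate),
      colorMode = colorMode)
}

#' RoiSet: the four analysis regions
#'
#' Named rectangular regions of interest laid out on the first frame and
#' reused for every frame: the two cheeks and forehead (cardiac signal) and
#' the upper torso (respiratory signal). Coordinates are 0-based with the
#' top-left origin; a rectangle spans columns `[x0, x0 + width)` and rows
#' `[y0, y0 + height)` (end-exclusive).
#'
#' @slot rois data.frame with columns label, x0, y0, width, height.
#' @slot source `"auto"` (detector-derived) or `"manual"`.
#' @export
setClass("RoiSet",
  representation(rois = "data.frame", source = "character"),
  validity = function(object) {
    msg <- NULL
    r <- object@rois
    need <- c("label", "x0", "y0", "width", "height")
    if (!all(need %in% names(r)))
      return("rois needs columns label, x0, y0, width, height")
    if (!setequal(r$label, ROI_LABELS))
      msg <- c(msg, "rois must contain exactly LCheek, FHead, RCheek, Torso")
    if (any(r$width < 4) || any(r$height < 4))
      msg <- c(msg, "ROI width and height must be at least 4 px")
    face <- r[r$label %in% FACE_ROI_LABELS, , drop = FALSE]
    if (nrow(face) == 3L) {
      for (i in 1:2) for (j in (i + 1):3) {
        a <- face[i, ]; b <- face[j, ]
        if (a$x0 < b$x0 + b$width && b$x0 < a$x0 + a$width &&
            a$y0 < b$y0 + b$height && b$y0 < a$y0 + a$height)
          msg <- c(msg, sprintf("face ROIs %s and %s overlap",
                                a$label, b$label))
      }
    }
    if (!object@source %in% c("auto", "manual"))
      msg <- c(msg, "source must be 'auto' or 'manual'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RoiSet
#'
#' @param rois data.frame with columns label, x0, y0, width, height
#'   (0-based, top-left origin, end-exclusive extents).
#' @param source `"auto"` or `"manual"`.
#' @return A [RoiSet-class] object.
#' @export
roiSet <- function(rois, source = "manual") {
  rois$label <- as.character(rois$label)
  for (col in c("x0", "y0", "width", "height"))
    rois[[col]] <- as.integer(round(rois[[col]]))
  new("RoiSet", rois = rois[, c("label", "x0", "y0", "width", "height")],
      source = source)
}

#' RgbTrace: spatially averaged channel intensities for one ROI
#'
#' The per-frame spatial mean of the red, green and blue channels over one
#' region of interest: the raw three-dimensional r-PPG observation
#' \eqn{x(i) = [x_R(i); x_G(i); x_B(i)]}, \eqn{i = 1, \dots, N}.
#'
#' @slot t sample times (s).
#' @slot xR,xG,xB mean channel intensities (counts).
#' @slot roiLabel which ROI the trace came from.
#' @export
setClass("RgbTrace",
  representation(t = "numeric", xR = "numeric", xG = "numeric",
                 xB = "numeric", roiLabel = "character"),
  validity = function(object) {
    n <- length(object@t)
    if (length(object@xR) != n || length(object@xG) != n ||
        length(object@xB) != n)
      return("t, xR, xG, xB must have equal length")
    if (anyNA(c(object@xR, object@xG, object@xB)))
      return("channel traces must be finite")
    TRUE
  })

#' Construct an RgbTrace
#' @param t sample times (s).
#' @param xR,xG,xB mean channel intensity series (counts).
#' @param roiLabel ROI name the trace came from.
#' @return An [RgbTrace-class] object.
#' @export
rgbTrace <- function(t, xR, xG, xB, roiLabel = "FHead")
  new("RgbTrace", t = as.numeric(t), xR = as.numeric(xR),
      xG = as.numeric(xG), xB = as.numeric(xB), roiLabel = roiLabel)

#' DisplacementTrace: the respiratory displacement signal
#'
#' The chest-wall displacement \eqn{s_y} obtained by integrating the
#' ROI-averaged vertical optical-flow velocity \eqn{v_y}, one sample per
#' frame pair, uniformly sampled at the frame rate. Units are proportional
#' to pixels; the sign is arbitrary (image y grows downward) and rate
#' estimation is polarity-invariant.
#'
#' @slot t sample times (s).
#' @slot sy displacement series.
#' @slot vyMean per-frame mean vertical velocity (px / frame).
#' @export
setClass("DisplacementTrace",
  representation(t = "numeric", sy = "numeric", vyMean = "numeric"),
  validity = function(object) {
    if (length(object@t) != length(object@sy) ||
        length(object@t) != length(object@vyMean))
      return("t, sy, vyMean must have equal length")
    TRUE
  })

#' Construct a DisplacementTrace
#' @param t sample times (s).
#' @param sy displacement series (arbitrary units proportional to px).
#' @param vyMean per-frame-pair mean vertical velocity (px/frame).
#' @return A [DisplacementTrace-class] object.
#' @export
displacementTrace <- function(t, sy, vyMean = rep(NA_real_, length(t)))
  new("DisplacementTrace", t = as.numeric(t), sy = as.numeric(sy),
      vyMean = as.numeric(vyMean))

#' PulseSignal: a one-dimensional candidate pulse waveform
#'
#' The output of one r-PPG post-processing technique applied to one ROI's
#' RGB trace: zero-mean, band-limited to the cardiac band after
#' conditioning.
#'
#' @slot t sample times (s).
#' @slot value dimensionless pulse series.
#' @slot method one of Green, MODW, CHROM, POS, ICA, PCA.
#' @slot roiLabel originating ROI.
#' @slot componentIndex selected component (ICA/PCA only; NA otherwise).
#' @export
setClass("PulseSignal",
  representation(t = "numeric", value = "numeric", method = "character",
                 roiLabel = "character", componentIndex = "integer"),
  validity = function(object) {
    if (length(object@t) != length(object@value))
      return("t and value must have equal length")
    if (!object@method %in% RPPG_METHODS)
      return(sprintf("method must be one of %s",
                     paste(RPPG_METHODS, collapse = ", ")))
    TRUE
  })

pulseSignal <- function(t, value, method, roiLabel,
                        componentIndex = NA_integer_)
  new("PulseSignal", t = as.numeric(t), value = as.numeric(value),
      method = method, roiLabel = roiLabel,
      componentIndex = as.integer(componentIndex))

#' RateSeries: per-second heart-rate or respiratory-rate estimates
#'
#' One rate estimate per sliding-window position (timestamped at the window
#' end), with a flag marking samples that were replaced during outlier
#' screening.
#'
#' @slot t window end times (s).
#' @slot rate estimates (bpm for HR, breaths/min for fR).
#' @slot outlier logical, TRUE where the value was replaced.
#' @slot source label: "method:roi" for single-ROI series, or a fusion
#'   label ("multi", "snr:roi").
#' @export
setClass("RateSeries",
  representation(t = "numeric", rate = "numeric", outlier = "logical",
                 source = "character"),
  validity = function(object) {
    if (length(object@t) != length(object@rate) ||
        length(object@t) != length(object@outlier))
      return("t, rate, outlier must have equal length")
    TRUE
  })

#' Construct a RateSeries
#' @param t window end times (s).
#' @param rate rate estimates (bpm or breaths/min).
#' @param outlier logical flags for replaced samples.
#' @param source provenance label.
#' @return A [RateSeries-class] object.
#' @export
rateSeries <- function(t, rate, outlier = rep(FALSE, length(t)),
                       source = "unknown")
  new("RateSeries", t = as.numeric(t), rate = as.numeric(rate),
      outlier = as.logical(outlier), source = source)

#' AgreementReport: Bland-Altman and error statistics
#'
#' Agreement between an estimated and a reference rate series: the mean of
#' differences (MOD), the half-width of the 95% limits of agreement
#' (1.96 x SD of differences), mean absolute error, root-mean-square error
#' and the coefficient of determination (squared Pearson correlation).
#'
#' @slot mod mean of differences (estimate - reference).
#' @slot loaHalfWidth 1.96 x sample SD of differences.
#' @slot mae mean absolute error.
#' @slot rmse root-mean-square error.
#' @slot r2 squared Pearson correlation (NA if the reference is constant).
#' @slot n number of paired samples.
#' @export
setClass("AgreementReport",
  representation(mod = "numeric", loaHalfWidth = "numeric", mae = "numeric",
                 rmse = "numeric", r2 = "numeric", n = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@mae < 0 || object@rmse < 0)
      msg <- c(msg, "mae and rmse must be non-negative")
    if (object@rmse < object@mae - 1e-9)
      msg <- c(msg, "rmse must be >= mae")
    if (object@loaHalfWidth < 0)
      msg <- c(msg, "loaHalfWidth must be non-negative")
    if (!is.na(object@r2) && (object@r2 < -1e-12 || object@r2 > 1 + 1e-12))
      msg <- c(msg, "r2 must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' SceneConfig: parameters of a synthetic test scene
#'
#' Describes a synthetic recording of a seated subject: a skin-toned face
#' patch whose channel intensities are modulated sinusoidally at the cardiac
#' frequency, and a textured torso band translating vertically at the
#' respiratory frequency, optionally preceded by a motionless (pulse-only)
#' apnea segment used for synchronization tests. All randomness is governed
#' by `seed`; identical configurations render bit-identical frames.
#'
#' @slot frameRate frames per second (Hz).
#' @slot duration recording length (s).
#' @slot frameSize integer (width, height) in pixels.
#' @slot hrTrue ground-truth heart rate (bpm), inside (30, 150).
#' @slot frTrue ground-truth respiratory rate (breaths/min), inside (3, 120).
#' @slot pulseAmpRgb relative modulation amplitude per channel, each in
#'   [0, 0.2].
#' @slot respAmp peak chest displacement (px).
#' @slot trendAmp slow illumination drift amplitude (counts).
#' @slot trendPeriod illumination drift period (s).
#' @slot noiseSd per-pixel Gaussian sensor noise SD (counts).
#' @slot apneaDuration motionless prefix length (s); 0 for none.
#' @slot seed RNG seed.
#' @export
setClass("SceneConfig",
  representation(frameRate = "numeric", duration = "numeric",
                 frameSize = "integer", hrTrue = "numeric",
                 frTrue = "numeric", pulseAmpRgb = "numeric",
                 respAmp = "numeric", trendAmp = "numeric",
                 trendPeriod = "numeric", noiseSd = "numeric",
                 apneaDuration = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@frameRate <= 0 || object@duration <= 0)
      msg <- c(msg, "frameRate and duration must be positive")
    if (length(object@frameSize) != 2L || any(object@frameSize < 8L))
      msg <- c(msg, "frameSize must be (width, height), each >= 8 px")
    if (object@hrTrue <= 30 || object@hrTrue >= 150)
      msg <- c(msg, "hrTrue must lie inside (30, 150) bpm")
    if (object@frTrue <= 3 || object@frTrue >= 120)
      msg <- c(msg, "frTrue must lie inside (3, 120) breaths/min")
    if (length(object@pulseAmpRgb) != 3L ||
        any(object@pulseAmpRgb < 0) || any(object@pulseAmpRgb > 0.2))
      msg <- c(msg, "pulseAmpRgb must be 3 amplitudes in [0, 0.2]")
    if (object@respAmp < 0 || object@noiseSd < 0 || object@trendAmp < 0)
      msg <- c(msg, "respAmp, trendAmp, noiseSd must be non-negative")
    if (object@trendPeriod <= 0)
      msg <- c(msg, "trendPeriod must be positive")
    if (object@apneaDuration < 0 || object@apneaDuration >= object@duration)
      msg <- c(msg, "apneaDuration must be in [0, duration)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SceneConfig
#'
#' Defaults reproduce the nominal study conditions: 1280 x 720 px at
#' 30 fps, 60 s, a ~5 s initial apnea, a resting heart rate of 72 bpm and
#' a respiratory rate of 15 breaths/min, with channel modulation strongest
#' in green (where the blood-volume pulse is strongest), a sub-percent
#' pulsatile amplitude, a ~2-pixel chest excursion and moderate sensor
#' noise. Note the frame size drives the ROI pixel counts and hence the
#' noise-averaging gain of [renderTraces()]; rendering actual pixels at
#' the full default size is memory-hungry, so pixel-level work typically
#' passes a smaller `frameSize` explicitly.
#'
#' @param frameRate frames per second (Hz).
#' @param duration recording length (s).
#' @param frameSize integer (width, height) in pixels.
#' @param hrTrue heart rate (bpm).
#' @param frTrue respiratory rate (breaths/min).
#' @param pulseAmpRgb relative channel modulation amplitudes.
#' @param respAmp peak chest displacement (px).
#' @param trendAmp illumination drift amplitude (counts).
#' @param trendPeriod illumination drift period (s).
#' @param noiseSd sensor noise SD (counts).
#' @param apneaDuration motionless prefix (s).
#' @param seed RNG seed.
#' @return A [SceneConfig-class] object.
#' @examples
#' cfg <- sceneConfig(duration = 30, hrTrue = 66)
#' @export
sceneConfig <- function(frameRate = 30, duration = 60,
                        frameSize = c(1280L, 720L), hrTrue = 72,
                        frTrue = 15,
                        pulseAmpRgb = c(0.004, 0.008, 0.004), respAmp = 2,
                        trendAmp = 2, trendPeriod = 30, noiseSd = 2,
                        apneaDuration = 5, seed = 1L)
  new("SceneConfig", frameRate = frameRate, duration = duration,
      frameSize = as.integer(round(frameSize)), hrTrue = hrTrue,
      frTrue = frTrue, pulseAmpRgb = pulseAmpRgb, respAmp = respAmp,
      trendAmp = trendAmp, trendPeriod = trendPeriod, noiseSd = noiseSd,
      apneaDuration = apneaDuration, seed = as.integer(seed))

#' SpectralConfig: sliding-window spectral analysis settings
#'
#' @slot windowS window length (s); 20 s by default.
#' @slot stepS slide step (s); 1 s by default.
#' @slot gridHz frequency grid resolution (Hz); 0.01 Hz (0.6 bpm).
#' @slot band search band (f_lo, f_hi) in Hz.
#' @export
setClass("SpectralConfig",
  representation(windowS = "numeric", stepS = "numeric", gridHz = "numeric",
                 band = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@windowS <= 0 || object@stepS <= 0 || object@gridHz <= 0)
      msg <- c(msg, "windowS, stepS, gridHz must be positive")
    if (object@stepS > object@windowS)
      msg <- c(msg, "stepS must not exceed windowS")
    if (length(object@band) != 2L || object@band[1L] <= 0 ||
        object@band[2L] <= object@band[1L])
      msg <- c(msg, "band must be (f_lo, f_hi) with 0 < f_lo < f_hi")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SpectralConfig
#'
#' @param windowS window length (s).
#' @param stepS slide step (s).
#' @param gridHz frequency grid resolution (Hz).
#' @param band search band (f_lo, f_hi) in Hz; the cardiac default
#'   0.5-2.5 Hz corresponds to 30-150 bpm, the respiratory band is
#'   0.05-2 Hz (3-120 breaths/min).
#' @return A [SpectralConfig-class] object.
#' @export
spectralConfig <- function(windowS = 20, stepS = 1, gridHz = 0.01,
                           band = c(0.5, 2.5))
  new("SpectralConfig", windowS = windowS, stepS = stepS, gridHz = gridHz,
      band = band)

CARDIAC_BAND <- c(0.5, 2.5)      # Hz, equivalent to 30-150 bpm
RESPIRATORY_BAND <- c(0.05, 2)   # Hz, equivalent to 3-120 breaths/min
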