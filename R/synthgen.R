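#' @include AllClasses.R roi_detect.R
NULL

# Evaluate a function under a fixed RNG seed, restoring the caller's
# RNG state afterwards, so generation never perturbs user randomness.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Fixed scene palette: intensities in 8-bit counts.
SKIN_BASE <- c(R = 180, G = 130, B = 110)
BACKGROUND_LEVEL <- 60
TORSO_BASE <- 90

# Deterministic geometric layout of the synthetic scene for a given frame
# size: a centred skin-toned face box in the upper part of the frame and a
# torso band that fills the frame below the face. Returns 0-based
# rectangles (top-left origin, end-exclusive).
sceneLayout <- function(frameSize) {
  W <- frameSize[1L]; H <- frameSize[2L]
  faceW <- round(0.30 * W); faceH <- round(0.35 * H)
  faceX0 <- round((W - faceW) / 2); faceY0 <- round(0.08 * H)
  bandY0 <- faceY0 + faceH + round(0.10 * faceH)
  list(face = c(x0 = faceX0, y0 = faceY0, width = faceW, height = faceH),
       bandY0 = bandY0, bandY1 = H)   # band rows [bandY0, H), 0-based
}

# Low-contrast fixed skin texture (counts), a smooth deterministic pattern
# so both spatial averaging and optical flow have structure to work with.
skinTexture <- function(rows, cols) {
  2 * outer(sin(2 * pi * rows / 7), cos(2 * pi * cols / 9))
}

# Vertical intensity profile of the torso band: a sum of Gaussian stripes
# ("shirt folds") whose translation by the respiratory displacement is
# rendered exactly by evaluating the profile at shifted row coordinates.
# y is 0-based row position relative to the band top.
torsoStripeProfile <- function(y, bandHeight) {
  # stripe tails (3 sigma) plus the displacement excursion stay inside
  # the band, so translation never moves stripe mass through its edges
  centers <- bandHeight * c(0.25, 0.45, 0.65)
  amps <- c(100, 60, 45)
  sigmas <- c(3, 2.5, 3.5)
  out <- numeric(length(y))
  for (k in seq_along(centers))
    out <- out + amps[k] * exp(-((y - centers[k])^2) / (2 * sigmas[k]^2))
  out
}

# Horizontal modulation of the stripe profile; multiplicative so that the
# intensity-weighted vertical centroid of the band tracks the displacement
# exactly.
torsoColumnGain <- function(cols) 1 + 0.15 * sin(2 * pi * cols / 17)

# Per-frame analytic signals shared by the pixel renderer and the
# trace-level shortcut.
sceneSignals <- function(config) {
  n <- round(config@duration * config@frameRate)
  t <- (seq_len(n) - 1) / config@frameRate
  phase <- 2 * pi * config@hrTrue / 60 * t
  pulse <- sin(phase)
  trend <- if (config@trendAmp > 0)
    config@trendAmp * sin(2 * pi * t / config@trendPeriod) else numeric(n) * 0
  breathing <- t >= config@apneaDuration
  disp <- ifelse(breathing,
                 config@respAmp *
                   sin(2 * pi * config@frTrue / 60 *
                         (t - config@apneaDuration)),
                 0)
  list(n = n, t = t, phase = phase, pulse = pulse, trend = trend,
       displacement = disp)
}

# Ground-truth ROI rectangles for a scene: the analysis layout applied to
# the true face box (near mode, since the synthetic face is large in frame).
sceneGroundTruthRois <- function(config) {
  lay <- sceneLayout(config@frameSize)
  placeRois(lay$face, frameSize = config@frameSize, mode = "near")
}

#' Render a synthetic scene with known ground truth
#'
#' Renders an RGB frame stack containing (a) a skin-toned face box whose
#' channel intensities are modulated as
#' \eqn{\mathrm{base}_c (1 + a_c \sin(2\pi\,\mathrm{HR}/60\, t))} plus a slow
#' illumination trend and i.i.d. Gaussian sensor noise, quantized to 8 bits,
#' and (b) a textured torso band translated vertically by
#' \eqn{A \sin(2\pi f_R/60 (t - t_\mathrm{apnea}))}, frozen during the
#' apnea prefix. Identical configurations (same seed) give bit-identical
#' frames.
#'
#' @param config a [SceneConfig-class].
#' @return A list with elements `frames` (a [FrameSequence-class]) and
#'   `groundTruth`: a list holding `signals` (data.frame with frame_index,
#'   time_s, displacement_px, pulse_phase_rad), `rois` (the ground-truth
#'   [RoiSet-class]), `faceBox` (0-based rectangle), `apneaEndFrame`,
#'   `apneaEndTime` and `config`.
#' @examples
#' sc <- renderScene(sceneConfig(duration = 4, frameSize = c(96, 72),
#'                               apneaDuration = 1))
#' sc$frames
#' @export
renderScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  W <- config@frameSize[1L]; H <- config@frameSize[2L]
  lay <- sceneLayout(config@frameSize)
  rois <- tryCatch(sceneGroundTruthRois(config), error = function(e)
    stop("configuration error: frame_size too small to host all four ROIs (",
         conditionMessage(e), ")", call. = FALSE))
  sig <- sceneSignals(config)
  n <- sig$n

  fr <- lay$face
  faceRows <- (fr["y0"] + 1):(fr["y0"] + fr["height"])
  faceCols <- (fr["x0"] + 1):(fr["x0"] + fr["width"])
  faceTex <- skinTexture(faceRows, faceCols)
  bandRows <- (lay$bandY0 + 1):lay$bandY1
  bandHeight <- length(bandRows)
  colGain <- torsoColumnGain(seq_len(W))

  base <- array(BACKGROUND_LEVEL, dim = c(H, W, 3L))
  for (ch in 1:3) {
    base[faceRows, faceCols, ch] <- SKIN_BASE[ch] + faceTex
    base[bandRows, , ch] <- TORSO_BASE
  }

  frames <- array(0L, dim = c(H, W, 3L, n))
  withSeed(config@seed, {
    for (f in seq_len(n)) {
      frame <- base
      pf <- 1 + config@pulseAmpRgb * sig$pulse[f]
      for (ch in 1:3)
        frame[faceRows, faceCols, ch] <-
          (SKIN_BASE[ch] + faceTex) * pf[ch]
      yRel <- (seq_len(bandHeight) - 1) - sig$displacement[f]
      stripe <- torsoStripeProfile(yRel, bandHeight)
      band <- TORSO_BASE + outer(stripe, colGain)
      for (ch in 1:3) frame[bandRows, , ch] <- band
      frame <- frame + sig$trend[f]
      if (config@noiseSd > 0)
        frame <- frame + rnorm(length(frame), sd = config@noiseSd)
      frames[, , , f] <- pmin.int(pmax.int(as.integer(round(frame)), 0L),
                                  255L)
    }
  })

  apneaEndFrame <- if (config@apneaDuration > 0)
    sum(sig$t < config@apneaDuration) else 0L
  gt <- list(
    signals = data.frame(frame_index = seq_len(n), time_s = sig$t,
                         displacement_px = sig$displacement,
                         pulse_phase_rad = sig$phase),
    rois = rois, faceBox = lay$face,
    apneaEndFrame = as.integer(apneaEndFrame),
    apneaEndTime = config@apneaDuration, config = config)
  list(frames = frameSequence(frames, config@frameRate, "rgb"),
       groundTruth = gt)
}

#' Render the analytic traces a scene embeds, without pixels
#'
#' A trace-level shortcut for fast experiments: returns the same channel
#' mean and displacement signals a rendered scene would yield, sampled at
#' the frame rate, with the sensor noise scaled by the square root of the
#' face-ROI pixel count (the averaging gain a real spatial mean enjoys).
#'
#' @param config a [SceneConfig-class].
#' @return A list with `traces` (named list of [RgbTrace-class] for LCheek,
#'   FHead, RCheek, each with independent noise), `displacement`
#'   (a [DisplacementTrace-class]) and `groundTruth` (as in
#'   [renderScene()], minus pixel-dependent fields).
#' @examples
#' tr <- renderTraces(sceneConfig(duration = 30))
#' tr$traces$FHead
#' @export
renderTraces <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  sig <- sceneSignals(config)
  rois <- sceneGroundTruthRois(config)
  side2 <- getRoi(rois, "FHead")$width * getRoi(rois, "FHead")$height
  sdTrace <- config@noiseSd / sqrt(side2)
  traces <- withSeed(config@seed, {
    out <- list()
    for (lab in FACE_ROI_LABELS) {
      r <- getRoi(rois, lab)
      # spatial mean of the fixed skin texture over this ROI, so the
      # trace matches the pixel renderer's ROI mean exactly
      texMean <- mean(skinTexture(roiRows(r), roiCols(r)))
      ch <- lapply(1:3, function(c_i)
        (SKIN_BASE[c_i] + texMean) *
          (1 + config@pulseAmpRgb[c_i] * sig$pulse) + sig$trend +
          if (sdTrace > 0) rnorm(sig$n, sd = sdTrace) else 0)
      out[[lab]] <- rgbTrace(sig$t, ch[[1L]], ch[[2L]], ch[[3L]],
                             roiLabel = lab)
    }
    out
  })
  vy <- c(0, diff(sig$displacement)) # px per frame
  disp <- displacementTrace(sig$t, sig$displacement, vy)
  apneaEndFrame <- if (config@apneaDuration > 0)
    sum(sig$t < config@apneaDuration) else 0L
  gt <- list(
    signals = data.frame(frame_index = seq_len(sig$n), time_s = sig$t,
                         displacement_px = sig$displacement,
                         pulse_phase_rad = sig$phase),
    rois = rois, apneaEndFrame = as.integer(apneaEndFrame),
    apneaEndTime = config@apneaDuration, config = config)
  list(traces = traces, displacement = disp, groundTruth = gt)
}

#' Write a rendered scene to disk
#'
#' Writes frames as zero-padded, losslessly encoded PNG files
#' (`frame_000001.png`, ...), the ground-truth signals as
#' `groundtruth.csv` (frame_index, time_s, displacement_px,
#' pulse_phase_rad), the ground-truth ROIs as `rois.csv` and the scene
#' configuration as a `config.yaml` sidecar.
#'
#' @param scene the list returned by [renderScene()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seq <- scene$frames
  n <- nFrames(seq)
  for (f in seq_len(n)) {
    img <- getFrame(seq, f) / 255
    png::writePNG(img, file.path(dir, sprintf("frame_%06d.png", f)))
  }
  write.csv(scene$groundTruth$signals, file.path(dir, "groundtruth.csv"),
            row.names = FALSE)
  writeRoiCsv(scene$groundTruth$rois, file.path(dir, "rois.csv"))
  cfg <- scene$groundTruth$config
  yaml::write_yaml(list(
    frame_rate = cfg@frameRate, duration = cfg@duration,
    frame_size = as.integer(cfg@frameSize), hr_true = cfg@hrTrue,
    fr_true = cfg@frTrue, pulse_amp_rgb = cfg@pulseAmpRgb,
    resp_amp = cfg@respAmp, trend_amp = cfg@trendAmp,
    trend_period = cfg@trendPeriod, noise_sd = cfg@noiseSd,
    apnea_duration = cfg@apneaDuration, seed = cfg@seed),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
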