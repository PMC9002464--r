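# Shared fixtures: small synthetic scenes and utilities, built in code.

# A compact noiseless config for pixel-level tests.
quietScene <- function(duration = 4, noiseSd = 0, ...) {
  sceneConfig(duration = duration, frameSize = c(96L, 72L),
              noiseSd = noiseSd, trendAmp = 0, apneaDuration = 0, ...)
}

# Intersection-over-union of two 0-based rectangles c(x0, y0, w, h).
iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Amplitude of a sinusoid at frequency f fitted by least squares.
fittedAmplitude <- function(x, t, f) {
  co <- coef(lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(co[2]^2 + co[3]^2)
}

# FFT periodogram band power in [lo, hi] Hz.
bandPower <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= lo & f <= hi & f <= fs / 2])
}

# RgbTrace with a pulse on chosen channels plus optional noise/trend.
makeTrace <- function(fHz = 1.2, n = 1800, fs = 30,
                      amp = c(R = 0, G = 1, B = 0),
                      base = c(R = 180, G = 130, B = 110),
                      noiseSd = 0, roiLabel = "FHead") {
  t <- (seq_len(n) - 1) / fs
  s <- sin(2 * pi * fHz * t)
  mk <- function(ch) base[ch] + amp[ch] * s +
    if (noiseSd > 0) rnorm(n, sd = noiseSd) else 0
  rgbTrace(t, mk("R"), mk("G"), mk("B"), roiLabel = roiLabel)
}
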