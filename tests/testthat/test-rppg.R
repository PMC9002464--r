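test_that("RGB traces are the spatial channel means of the ROI", {
  fr <- array(0, dim = c(20, 20, 3, 2))
  fr[, , 1, ] <- 10; fr[, , 2, ] <- 20; fr[, , 3, ] <- 30
  # checkerboard of 0/255 in the green channel
  chk <- outer(1:20, 1:20, function(i, j) ((i + j) %% 2) * 255)
  fr[, , 2, 2] <- chk
  seq <- frameSequence(fr, 30)
  roi <- data.frame(label = "FHead", x0 = 4, y0 = 4, width = 8,
                    height = 8)
  tr <- extractRgbTrace(seq, roi)
  expect_equal(tr@xR, c(10, 10))
  expect_equal(tr@xB, c(30, 30))
  expect_equal(tr@xG[1], 20)
  expect_equal(tr@xG[2], 127.5)
  expect_error(extractRgbTrace(seq, data.frame(label = "x", x0 = 18,
    y0 = 0, width = 8, height = 8)), "outside")
})

test_that("SPA detrending removes trends and keeps in-band signal", {
  fs <- 30; t <- (0:899) / fs
  expect_lt(max(abs(detrendSpa(rep(7, 300)))), 1e-8 * 7)
  ramp <- 3 * t
  tone <- sin(2 * pi * 1.5 * t)
  d <- detrendSpa(ramp + tone)
  # cardiac-band power retained, measured against the pure tone (the
  # raw ramp's spectral leakage would otherwise contaminate the band)
  expect_gte(bandPower(d, fs, 1.3, 1.7) / bandPower(tone, fs, 1.3, 1.7),
             0.9)
  # ramp power removed, measured against the pure ramp
  expect_lte(bandPower(d, fs, 0.001, 0.1) /
               bandPower(ramp, fs, 0.001, 0.1), 0.01)
  # lambda -> 0: the smoother approaches identity, residual vanishes
  x <- ramp + tone
  expect_lt(max(abs(detrendSpa(x, lambda = 1e-4))), 1e-6 * max(abs(x)))
})

test_that("cardiac band-pass preserves in-band tones and kills stopband", {
  fs <- 30; t <- (0:(fs * 120 - 1)) / fs
  mid <- t > 30 & t < 90
  y <- bandpassCardiac(sin(2 * pi * 1.0 * t), fs)
  expect_equal(unname(fittedAmplitude(y[mid], t[mid], 1.0)), 1,
               tolerance = 0.05)
  y2 <- bandpassCardiac(sin(2 * pi * 0.2 * t), fs)
  expect_lt(fittedAmplitude(y2[mid], t[mid], 0.2), 0.01)  # >= 40 dB down
  expect_equal(bandpassCardiac(rep(0, 600), fs), rep(0, 600))
})

test_that("green-channel method passes the conditioned green through", {
  tr <- makeTrace(fHz = 1.2, amp = c(R = 0, G = 1, B = 0))
  p <- methodGreen(tr)
  psd <- lombPsd(pulseValues(p), sampleTimes(p), seq(0.5, 2.5, 0.01))
  expect_equal(psd$freq[which.max(psd$power)], 1.2, tolerance = 1e-9)
  expect_lt(abs(mean(pulseValues(p))), 1e-6 * sd(pulseValues(p)))
  # red-only modulation leaves nothing in the green channel
  pr <- methodGreen(makeTrace(fHz = 1.2, amp = c(R = 1, G = 0, B = 0)))
  expect_lt(sd(pulseValues(pr)), 1e-6 * sd(pulseValues(p)))
})

test_that("MODWT-MRA components sum back to the input exactly", {
  set.seed(5)
  x <- rnorm(512)
  m <- modwtMra(x)
  recon <- Reduce(`+`, m$details) + m$smooth
  expect_lt(max(abs(recon - x)), 1e-10)
})

test_that("MODWT level selection keeps cardiac tones, drops drift", {
  fs <- 30; t <- (0:1799) / fs
  tone <- sin(2 * pi * 1.2 * t)
  m <- modwtMra(tone)
  kept <- m$details[[3]] + m$details[[4]]   # 0.94-3.75 Hz at 30 fps
  expect_gte(fittedAmplitude(kept, t, 1.2) / fittedAmplitude(tone, t, 1.2),
             0.7)
  drift <- sin(2 * pi * 0.1 * t)
  md <- modwtMra(drift)
  keptD <- md$details[[3]] + md$details[[4]]
  expect_lte(fittedAmplitude(keptD, t, 0.1) /
               fittedAmplitude(drift, t, 0.1), 0.1)
  # method-level: 1.2 Hz green tone survives the full MODW path
  p <- methodModwt(makeTrace(fHz = 1.2, amp = c(R = 0, G = 1, B = 0)))
  psd <- lombPsd(pulseValues(p), sampleTimes(p), seq(0.5, 2.5, 0.01))
  expect_equal(psd$freq[which.max(psd$power)], 1.2, tolerance = 1e-9)
  expect_error(modwt(rnorm(50), 4), "too short")
})

test_that("CHROM is scale-invariant and projects out constant colour", {
  set.seed(7)
  tr <- makeTrace(fHz = 1.1, amp = c(R = 0.3, G = 1, B = 0.2),
                  noiseSd = 0.2)
  p1 <- methodChrom(tr)
  k <- 3.7   # all channels scaled by one constant: identical output
  tr2 <- rgbTrace(tr@t, k * tr@xR, k * tr@xG, k * tr@xB, tr@roiLabel)
  p2 <- methodChrom(tr2)
  expect_equal(pulseValues(p1), pulseValues(p2), tolerance = 1e-9)
  # constant channels produce (numerically) nothing
  tc <- makeTrace(fHz = 1.1, amp = c(R = 0, G = 0, B = 0))
  expect_lt(sd(pulseValues(methodChrom(tc))), 1e-9)
  # green-only modulation: peak frequency preserved by the projection
  pg <- methodChrom(makeTrace(fHz = 1.3, amp = c(R = 0, G = 0.8, B = 0)))
  psd <- lombPsd(pulseValues(pg), sampleTimes(pg), seq(0.5, 2.5, 0.01))
  expect_equal(psd$freq[which.max(psd$power)], 1.3, tolerance = 1e-9)
})

test_that("POS cancels common-mode flicker but keeps pulse chrominance", {
  fs <- 30; n <- 1800; t <- (0:(n - 1)) / fs
  expect_lt(sd(pulseValues(methodPos(makeTrace(amp = c(R = 0, G = 0,
    B = 0))))), 1e-9)
  # flicker: identical relative modulation on all channels
  m <- 0.01 * sin(2 * pi * 1.4 * t)
  flick <- rgbTrace(t, 180 * (1 + m), 130 * (1 + m), 110 * (1 + m))
  pulse <- makeTrace(fHz = 1.4, amp = c(R = 0, G = 130 * 0.01, B = 0))
  bpF <- bandPower(pulseValues(methodPos(flick)), fs, 1.2, 1.6)
  bpP <- bandPower(pulseValues(methodPos(pulse)), fs, 1.2, 1.6)
  expect_gte(bpP / bpF, 10)
  # end-to-end: 90 bpm scene trace peaks at 1.5 Hz
  tl <- renderTraces(sceneConfig(hrTrue = 90, seed = 21))
  p <- methodPos(tl$traces$FHead)
  psd <- lombPsd(pulseValues(p), sampleTimes(p), seq(0.5, 2.5, 0.01))
  expect_equal(psd$freq[which.max(psd$power)], 1.5, tolerance = 1e-9)
})

test_that("JADE separates a known mixture up to sign and permutation", {
  set.seed(42)
  t <- (0:1799) / 30
  src <- rbind(sin(2 * pi * 1.2 * t), rnorm(1800),
               sin(2 * pi * 0.05 * t))
  A <- matrix(rnorm(9), 3)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3)
  fit <- jadeIca(A %*% src)
  best <- max(abs(cor(t(fit$S), src[1, ])))
  expect_gte(best, 0.9)
})

test_that("BSS component selection finds the pulse and is deterministic", {
  tl <- renderTraces(sceneConfig(hrTrue = 66, seed = 3))
  for (kind in c("ICA", "PCA")) {
    p <- applyMethod(kind, tl$traces$FHead)
    expect_false(is.na(p@componentIndex))
    psd <- lombPsd(pulseValues(p), sampleTimes(p), seq(0.5, 2.5, 0.01))
    expect_equal(psd$freq[which.max(psd$power)], 1.1, tolerance = 1e-9)
    p2 <- applyMethod(kind, tl$traces$FHead)
    expect_identical(pulseValues(p), pulseValues(p2))
  }
})

test_that("PCA selects the dominant-variance axis carrying the pulse", {
  set.seed(9)
  t <- (0:1799) / 30
  s <- 5 * sin(2 * pi * 1.2 * t)
  tr <- rgbTrace(t, 180 + s + rnorm(1800, sd = 0.01),
                 130 + s + rnorm(1800, sd = 0.01),
                 110 + s + rnorm(1800, sd = 0.01))
  p <- methodBss(tr, "PCA")
  expect_equal(p@componentIndex, 1L)
  expect_gte(abs(cor(pulseValues(p), bandpassCardiac(s, 30))), 0.99)
})

test_that("degenerate identical channels fall back to the green channel", {
  t <- (0:899) / 30
  x <- 130 + sin(2 * pi * 1.2 * t)
  tr <- rgbTrace(t, x, x, x)
  expect_warning(p <- methodBss(tr, "ICA"), "rank-deficient")
  expect_true(is.na(p@componentIndex))
  expect_equal(p@method, "ICA")
  expect_gte(abs(cor(pulseValues(p),
                     pulseValues(methodGreen(tr)))), 0.999)
})

test_that("all methods shift-invariance: adding a constant to every channel", {
  set.seed(13)
  tr <- makeTrace(fHz = 1.2, amp = c(R = 0.2, G = 1, B = 0.1),
                  noiseSd = 0.3)
  shifted <- rgbTrace(tr@t, tr@xR + 25, tr@xG + 25, tr@xB + 25,
                      tr@roiLabel)
  for (m in c("Green", "MODW", "ICA", "PCA")) {
    a <- pulseValues(applyMethod(m, tr))
    b <- pulseValues(applyMethod(m, shifted))
    expect_equal(a, b, tolerance = 1e-6)
  }
  # CHROM/POS renormalize by channel means, so the waveform shape (not
  # its scale) is preserved under a common offset
  for (m in c("CHROM", "POS")) {
    a <- pulseValues(applyMethod(m, tr))
    b <- pulseValues(applyMethod(m, shifted))
    expect_gte(abs(cor(a, b)), 0.99)
  }
})

test_that("every method recovers the scene heart rate at the Lomb peak", {
  tl <- renderTraces(sceneConfig(hrTrue = 72, seed = 17))
  for (m in c("Green", "MODW", "CHROM", "POS", "ICA", "PCA")) {
    p <- applyMethod(m, tl$traces$FHead)
    psd <- lombPsd(pulseValues(p), sampleTimes(p), seq(0.5, 2.5, 0.01))
    expect_equal(psd$freq[which.max(psd$power)], 1.2, tolerance = 1e-9,
                 label = paste("peak for", m))
  }
})
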