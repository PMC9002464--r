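# Oracle: best integer shift by cross-correlation of two images.
bestIntegerShift <- function(a, b, maxShift = 3) {
  shifts <- -maxShift:maxShift
  score <- vapply(shifts, function(s) {
    if (s >= 0) {
      aa <- a[seq_len(nrow(a) - s), , drop = FALSE]
      bb <- b[(1 + s):nrow(b), , drop = FALSE]
    } else {
      aa <- a[(1 - s):nrow(a), , drop = FALSE]
      bb <- b[seq_len(nrow(b) + s), , drop = FALSE]
    }
    cor(as.vector(aa), as.vector(bb))
  }, numeric(1))
  shifts[which.max(score)]
}

smoothTestImage <- function(H = 60, W = 80) {
  outer(seq_len(H), seq_len(W),
        function(y, x) 100 + 2 * y + 0.5 * x + 10 * sin(y / 4) * cos(x / 5))
}

test_that("identical frames give zero flow", {
  img <- smoothTestImage()
  f <- hornSchunck(img, img)
  expect_equal(max(abs(f$vx)), 0)
  expect_equal(max(abs(f$vy)), 0)
})

test_that("unit shifts are recovered against the cross-correlation oracle", {
  img <- smoothTestImage()
  H <- nrow(img); W <- ncol(img)
  down <- rbind(img[1, ], img[-H, ])     # content moves down one row
  expect_equal(bestIntegerShift(img, down), 1)   # oracle confirms +1 row
  f <- hornSchunck(img, down, nIter = 200, tol = 1e-4)
  interior <- f$vy[10:(H - 10), 10:(W - 10)]
  expect_equal(mean(interior), 1, tolerance = 0.1)

  right <- cbind(img[, 1], img[, -W])    # content moves right one column
  f2 <- hornSchunck(img, right, nIter = 200, tol = 1e-4)
  expect_equal(mean(f2$vx[10:(H - 10), 10:(W - 10)]), 1, tolerance = 0.1)
  expect_lt(max(abs(mean(f2$vy[10:(H - 10), 10:(W - 10)]))), 0.1)
})

test_that("flow responds linearly to subpixel shift doubling", {
  H <- 60; W <- 80
  shifted <- function(dy)
    outer(seq_len(H), seq_len(W),
          function(y, x) 100 + 20 * sin((y - dy) / 5) + 5 * cos(x / 6))
  base <- shifted(0)
  f1 <- hornSchunck(base, shifted(0.4), nIter = 300, tol = 1e-5)
  f2 <- hornSchunck(base, shifted(0.8), nIter = 300, tol = 1e-5)
  m1 <- mean(f1$vy[10:(H - 10), 10:(W - 10)])
  m2 <- mean(f2$vy[10:(H - 10), 10:(W - 10)])
  expect_gt(m2 / m1, 1.6)
  expect_lt(m2 / m1, 2.4)
})

test_that("mismatched frame shapes are rejected", {
  expect_error(hornSchunck(matrix(0, 4, 4), matrix(0, 4, 5)),
               "same shape")
})

test_that("ROI-mean vertical velocity equals direct summation", {
  set.seed(11)
  flow <- list(vx = matrix(rnorm(50 * 60), 50),
               vy = matrix(rnorm(50 * 60), 50))
  roi <- data.frame(label = "Torso", x0 = 12, y0 = 7, width = 20,
                    height = 30)
  direct <- 0
  for (i in 8:37) for (j in 13:32) direct <- direct + flow$vy[i, j]
  expect_equal(meanVerticalVelocity(flow, roi), direct / (20 * 30))
  # uniform and antisymmetric fields
  flow$vy[] <- 3.5
  expect_equal(meanVerticalVelocity(flow, roi), 3.5)
  flow$vy[, 13:22] <- 1; flow$vy[, 23:32] <- -1
  expect_equal(meanVerticalVelocity(flow, roi), 0)
  expect_error(meanVerticalVelocity(flow, data.frame(label = "T", x0 = 55,
    y0 = 0, width = 20, height = 10)), "outside")
})

test_that("velocity integrates by the trapezoid rule", {
  expect_equal(integrateVelocity(rep(0, 50), 30), rep(0, 50))
  s <- integrateVelocity(rep(1, 30), 30)
  expect_equal(s[30], 29 / 30)            # 29 intervals at dt = 1/30
  expect_equal(diff(s), rep(1 / 30, 29))
  # sinusoid matches the analytic antiderivative to O(dt^2)
  fs <- 30; t <- (0:599) / fs; f <- 0.5; A <- 2
  s2 <- integrateVelocity(A * sin(2 * pi * f * t), fs)
  expected <- -A / (2 * pi * f) * cos(2 * pi * f * t)
  expected <- expected - expected[1]
  expect_lt(max(abs(s2 - expected)), A * (2 * pi * f / fs)^2)
})

test_that("respiratory band-pass matches its analytic magnitude response", {
  fs <- 30
  t <- (0:(fs * 120 - 1)) / fs
  bf <- signal::butter(1, c(0.05, 2) / (fs / 2), type = "pass")
  gainAt <- function(f) {
    # evaluate the digital transfer function at f; forward-backward
    # application squares the magnitude
    z <- exp(-1i * 2 * pi * f / fs)
    k <- seq_along(bf$b) - 1
    Mod(sum(bf$b * z^k) / sum(bf$a * z^k))^2
  }
  mid <- t > 30 & t < 90   # avoid filter edge transients
  for (f in c(0.25, 1.9)) {
    y <- bandpassRespiratory(sin(2 * pi * f * t), fs)
    measured <- fittedAmplitude(y[mid], t[mid], f)
    expect_equal(unname(measured), gainAt(f), tolerance = 0.05)
  }
  # DC is outside the passband
  y0 <- bandpassRespiratory(rep(10, length(t)), fs)
  expect_lt(max(abs(y0[mid])), 0.5)
  # 5 Hz sits on the first-order rolloff
  y5 <- bandpassRespiratory(sin(2 * pi * 5 * t), fs)
  expect_equal(unname(fittedAmplitude(y5[mid], t[mid], 5)), gainAt(5),
               tolerance = 0.05)
  expect_error(bandpassRespiratory(rnorm(100), 4), "frameRate")
})

test_that("chest motion is recovered end-to-end from a rendered scene", {
  cfg <- sceneConfig(duration = 30, frTrue = 10, apneaDuration = 0,
                     noiseSd = 1, frameSize = c(160L, 120L))
  sc <- renderScene(cfg)
  dt <- extractRespiration(sc$frames, getRoi(sc$groundTruth$rois, "Torso"))
  expect_length(displacement(dt), nFrames(sc$frames) - 1)
  rs <- slidingRates(dt, spectralConfig(band = c(0.05, 2)))
  expect_equal(median(rateValues(rs)), 10, tolerance = 0.061)
  # one Lomb grid step at 0.01 Hz resolution = 0.6 breaths/min
  expect_true(all(abs(rateValues(rs) - 10) <= 0.6 + 1e-9))
})
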