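test_that("the Lomb periodogram locates single and dominant tones", {
  t <- (0:599) / 30
  grid <- seq(0.5, 2.5, by = 0.01)
  psd <- lombPsd(sin(2 * pi * 1.0 * t), t, grid)
  expect_equal(psd$freq[which.max(psd$power)], 1.00)
  two <- sin(2 * pi * 0.8 * t) + 0.3 * sin(2 * pi * 1.6 * t)
  psd2 <- lombPsd(two, t, grid)
  expect_equal(psd2$freq[which.max(psd2$power)], 0.80)
})

test_that("the Lomb periodogram tolerates nonuniform sampling", {
  set.seed(101)
  t <- (0:599) / 30
  keep <- sort(sample(600, 540))          # random 10% dropout
  psd <- lombPsd(sin(2 * pi * 1.0 * t)[keep], t[keep],
                 seq(0.5, 2.5, by = 0.01))
  expect_equal(psd$freq[which.max(psd$power)], 1.00)
})

test_that("a constant window yields a flagged flat spectrum and NA rate", {
  psd <- lombPsd(rep(3, 100), (0:99) / 30, seq(0.5, 2.5, 0.01))
  expect_true(attr(psd, "flat"))
  expect_true(all(psd$power == 0))
  expect_true(is.na(rateFromWindow(psd, c(0.5, 2.5))))
})

test_that("rates are 60x the in-band argmax frequency", {
  grid <- seq(0.05, 2.5, by = 0.01)
  mkPsd <- function(peak) {
    p <- data.frame(freq = grid, power = exp(-abs(grid - peak) * 50))
    attr(p, "flat") <- FALSE
    p
  }
  expect_equal(rateFromWindow(mkPsd(1.2), c(0.5, 2.5)), 72)
  expect_equal(rateFromWindow(mkPsd(2.5), c(0.5, 2.5)), 150)  # band edge
  expect_equal(rateFromWindow(mkPsd(0.5), c(0.5, 2.5)), 30)
  expect_equal(rateFromWindow(mkPsd(0.25), c(0.05, 2)), 15)
  # brute-force argmax oracle on a random spectrum
  set.seed(31)
  p <- data.frame(freq = grid, power = runif(length(grid)))
  attr(p, "flat") <- FALSE
  sel <- p$freq >= 0.5 & p$freq <= 2.5
  best <- -Inf; bestF <- NA
  for (i in which(sel)) if (p$power[i] > best) {
    best <- p$power[i]; bestF <- p$freq[i]
  }
  expect_equal(rateFromWindow(p, c(0.5, 2.5)), 60 * bestF)
})

test_that("window counts follow floor((T - window)/step) + 1 exactly", {
  fs <- 10
  mk <- function(T) {
    t <- (seq_len(T * fs) - 1) / fs
    list(x = sin(2 * pi * 1.0 * t) + 0.01 * t, t = t)
  }
  for (T in c(20, 25, 60)) for (w in c(10, 20)) for (s in c(1, 2, 5)) {
    cfg <- spectralConfig(windowS = w, stepS = s, gridHz = 0.05,
                          band = c(0.5, 2.5))
    sig <- mk(T)
    rs <- slidingRates(sig$x, cfg, t = sig$t)
    expect_equal(length(rateValues(rs)), floor((T - w) / s) + 1,
                 label = sprintf("window count for T=%g w=%g s=%g",
                                 T, w, s))
  }
  # a signal exactly one window long gives a single estimate
  sig <- mk(20)
  expect_length(rateValues(slidingRates(sig$x,
    spectralConfig(windowS = 20, gridHz = 0.05), t = sig$t)), 1)
  expect_error(slidingRates(mk(15)$x, spectralConfig(), t = mk(15)$t),
               "shorter")
})

test_that("sliding rates equal the explicit per-window Lomb oracle", {
  set.seed(61)
  fs <- 30; t <- (0:(30 * fs - 1)) / fs
  x <- sin(2 * pi * 1.17 * t) + 0.3 * rnorm(length(t))
  cfg <- spectralConfig(windowS = 10, stepS = 2)
  rs <- slidingRates(x, cfg, t = t)
  grid <- seq(0.5, 2.5, by = 0.01)
  manual <- vapply(seq_along(rateValues(rs)), function(k) {
    idx <- ((k - 1) * 2 * fs + 1):((k - 1) * 2 * fs + 10 * fs)
    rateFromWindow(lombPsd(x[idx], t[idx], grid), c(0.5, 2.5))
  }, numeric(1))
  expect_equal(rateValues(rs), manual)
})

test_that("sliding estimates track a chirp monotonically", {
  fs <- 30; T <- 60
  t <- (0:(T * fs - 1)) / fs
  f0 <- 1; f1 <- 1.5                      # 60 -> 90 bpm
  x <- sin(2 * pi * (f0 * t + (f1 - f0) / (2 * T) * t^2))
  rs <- slidingRates(x, spectralConfig(), t = t)
  expect_length(rateValues(rs), 41)
  expect_true(all(diff(rateValues(rs)) >= -0.6 - 1e-9))
})

test_that("outlier replacement matches the hand-computed fence oracle", {
  rs <- rateSeries(1:5, c(70, 71, 72, 73, 200))
  # type-7 quantiles: Q1 = 71, Q3 = 73, IQR = 2, fences [68, 76]
  out <- replaceOutliers(rs)
  expect_equal(rateValues(out), c(70, 71, 72, 73, 73))
  expect_equal(outlierFlags(out), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # all-equal series: IQR = 0, fences collapse onto the value, no change
  same <- rateSeries(1:6, rep(72, 6))
  expect_equal(rateValues(replaceOutliers(same)), rep(72, 6))
  expect_false(any(outlierFlags(replaceOutliers(same))))
  # in-fence series unchanged
  ok <- rateSeries(1:8, c(70, 72, 71, 73, 74, 72, 71, 70))
  expect_equal(rateValues(replaceOutliers(ok)), rateValues(ok))
})

test_that("outlier replacement is idempotent and order-preserving", {
  set.seed(77)
  for (rep in 1:20) {
    r <- 72 + rnorm(41, sd = 2)
    spikes <- sample(41, 3)
    r[spikes] <- r[spikes] + sample(c(-40, 40), 3, replace = TRUE)
    rs <- rateSeries(seq_along(r), r)
    once <- replaceOutliers(rs)
    twice <- replaceOutliers(once)
    expect_equal(rateValues(twice), rateValues(once))
    keep <- !outlierFlags(once)
    expect_equal(rateValues(once)[keep], r[keep])
  }
})

test_that("NA rates from flagged flat windows are filled before fusion", {
  rs <- rateSeries(1:6, c(70, NA, 72, 73, 71, 70))
  out <- replaceOutliers(rs)
  expect_equal(rateValues(out)[2], 70)   # nearest non-outlier, earlier wins
  expect_true(outlierFlags(out)[2])
})

test_that("multi-ROI fusion is the element-wise three-series mean", {
  t <- 20:60
  a <- rateSeries(t, rep(70, 41)); b <- rateSeries(t, rep(72, 41))
  c3 <- rateSeries(t, rep(74, 41))
  expect_equal(rateValues(fuseMultiRoi(a, b, c3)), rep(72, 41))
  expect_equal(rateValues(fuseMultiRoi(b, b, b)), rateValues(b))
  shifted <- rateSeries(t, rep(75, 41))   # +3 on one ROI -> +1 fused
  expect_equal(rateValues(fuseMultiRoi(shifted, b, b)),
               rateValues(fuseMultiRoi(b, b, b)) + 1)
  expect_error(fuseMultiRoi(a, b, rateSeries(21:61, rep(74, 41))),
               "time base")
})

test_that("spectral SNR behaves as expected for tones and noise", {
  fs <- 30; t <- (0:1799) / fs
  expect_gte(snrDb(sin(2 * pi * 1.5 * t), fs, fundamental = 1.5), 40)
  # tone far outside the template of a 2.0 Hz fundamental
  expect_lte(snrDb(sin(2 * pi * 0.6 * t), fs, fundamental = 2.0), -10)
  # white noise: flat-spectrum expectation from the template bin counts
  n <- length(t)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= 0.5 & f <= 4
  tmpl <- abs(f[keep] - 1.5) <= 0.1 | abs(f[keep] - 3.0) <= 0.1
  expected <- 10 * log10(sum(tmpl) / sum(!tmpl))
  set.seed(55)
  snrs <- vapply(1:100, function(i)
    snrDb(rnorm(n), fs, fundamental = 1.5), numeric(1))
  expect_lt(abs(mean(snrs) - expected), 3)
})

test_that("SNR-based selection prefers the clean ROI and breaks ties", {
  set.seed(4)
  t <- (0:1199) / 30
  clean <- pulseSignal(t, sin(2 * pi * 1.2 * t), "Green", "FHead")
  noisy1 <- pulseSignal(t, rnorm(1200), "Green", "LCheek")
  noisy2 <- pulseSignal(t, rnorm(1200), "Green", "RCheek")
  sel <- selectBySnr(list(noisy1, clean, noisy2))
  expect_equal(sel@roiLabel, "FHead")
  expect_equal(selectBySnr(list(clean))@roiLabel, "FHead")
  # exact tie between duplicated signals: RCheek has priority
  dupL <- pulseSignal(t, sin(2 * pi * 1.2 * t), "Green", "LCheek")
  dupR <- pulseSignal(t, sin(2 * pi * 1.2 * t), "Green", "RCheek")
  expect_equal(selectBySnr(list(dupL, dupR))@roiLabel, "RCheek")
})
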