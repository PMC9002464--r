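---
title: "Contactless cardio-respiratory monitoring: models and methods"
author: "pulsecam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless cardio-respiratory monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

A camera pointed at a seated person records two physiological signals
without any contact. First, breathing moves the chest wall: a torso
region of the image translates vertically by a couple of pixels at the
respiratory frequency. Second, each heart beat changes the blood volume
in facial skin capillaries, which modulates the light reflected from the
skin by a fraction of a percent — the remote photoplethysmographic
(r-PPG) signal, strongest in the green channel. pulsecam turns an RGB
frame sequence into per-second time series of respiratory rate (fR,
breaths/min) and heart rate (HR, bpm), plus agreement statistics against
a reference recording.

The pipeline is organized exactly as its stages are exposed in the API:

1. **ROI layout** (`detectFace()`, `placeRois()`): four rectangles fixed
   on the first frame — left cheek, forehead, right cheek (square, side
   5% of frame height for ~0.5 m recordings, 3% for ~1 m) and an upper
   torso box derived geometrically from the face box.
2. **Respiration** (`extractRespiration()`): Horn–Schunck optical flow
   between consecutive greyscale frames, ROI-mean vertical velocity,
   trapezoidal integration into the displacement `s_y`, first-order
   Butterworth band-pass 0.05–2 Hz (3–120 breaths/min), zero phase.
3. **r-PPG** (`extractRgbTrace()` + six methods): per-ROI channel means
   conditioned by smoothness-priors detrending and a fourth-order
   Butterworth band-pass 0.5–2.5 Hz (30–150 bpm), then reduced to one
   candidate pulse per technique: green channel, MODWT multiresolution
   reconstruction, CHROM and POS chrominance projections, JADE ICA and
   PCA with spectral-peak component selection.
4. **Rate estimation** (`slidingRates()`): Lomb periodogram in a 20 s
   window sliding by 1 s; the rate is 60 times the in-band argmax
   frequency, so a 60 s analysis span yields exactly 41 estimates.
5. **Outlier replacement and fusion** (`replaceOutliers()`,
   `fuseMultiRoi()`, `selectBySnr()`): Tukey 1.5 × IQR fences over the
   whole series with nearest-neighbour substitution; then either the
   three-ROI mean or the single ROI with the highest spectral SNR.
6. **Evaluation** (`detectApneaEndpoint()`, `alignAndCrop()`,
   `agreementReport()`): synchronization at the endpoint of an initial
   deliberate breath-hold, then Bland–Altman (MOD ± 1.96 SD), MAE, RMSE
   and R².

# Models and their assumptions

## Horn–Schunck optical flow

Brightness constancy gives \(I_x v_x + I_y v_y + I_t = 0\) per pixel;
the aperture problem is resolved by a global smoothness penalty weighted
by \(\alpha^2\). We minimize the classic discrete energy with the
4-point derivative stencils and the Jacobi-style fixed-point iteration
(neighbourhood weights 1/6 and 1/12). Assumptions worth keeping in mind:
motion must be small (well under a pixel per frame for accurate
magnitudes — chest motion at 30 fps easily qualifies), and illumination
must be stable between consecutive frames. The flow is computed on a
crop extending 12 px beyond the torso ROI rather than the full frame:
only the ROI-mean vertical velocity is consumed, and the smoothness
coupling decays within a few pixels, so the crop changes the mean by far
less than the estimator's own noise while making the cost independent of
frame size. Velocity magnitudes are biased toward zero by the
regularization; this is irrelevant here because rate estimation only
uses the dominant frequency, not the amplitude, of `s_y`.

## Conditioning: smoothness-priors detrending

The trend of each channel trace is estimated as
\((I + \lambda^2 D_2^\top D_2)^{-1} x\) (second-difference penalty) and
subtracted. The smoother is a low-pass whose cutoff moves down as
\(\lambda\) grows: the amplitude response of the detrend residual is
\(\lambda^2 a^2/(1 + \lambda^2 a^2)\) with \(a = 4\sin^2(\pi f/f_s)\),
so the half-power point sits where \(a = 1/\lambda\). The default
\(\lambda = 60\) places it near 0.62 Hz at 30 fps — just below the
cardiac band — retaining ≥ 90% of band power at a 1.5 Hz pulse (asserted
in the test suite) while removing ramps and slow illumination drifts
almost entirely. Small \(\lambda\) values (say 10) would erode the low
end of the cardiac band noticeably (gain ~0.07 at 0.8 Hz), which only
the peak-location invariance of the Lomb stage would mask. The solve
uses a sparse banded Cholesky factorization; the matrix is SPD so it
cannot fail. An optional linear detrend precedes it;
both are exposed because "detrending" and "smoothness priors" are
sometimes treated as one step and sometimes as two — here SPA *is* the
detrender and the linear pre-step is a cheap guard for very long ramps.

## The six r-PPG techniques

* **Green**: the conditioned green channel, passed through. The baseline
  every other technique must beat.
* **MODW**: maximal-overlap discrete wavelet transform (symlet-4,
  4 levels) with multiresolution analysis; the pulse estimate sums the
  components whose dyadic band \([f_s/2^{j+1}, f_s/2^j]\) intersects
  0.5–2.5 Hz — details 3 and 4 at 30 fps, plus the final smooth, whose
  band \([0, f_s/16]\) reaches 0.94 Hz and therefore still carries heart
  rates below ~56 bpm (without it, a 48 bpm pulse would be discarded
  with the drift). The closing band-pass strips the smooth's
  sub-cardiac content. MODWT is shift-invariant and its MRA is exactly
  additive (machine-precision reconstruction is asserted in the tests),
  so this is a well-behaved octave-band filter bank.
* **CHROM**: channels are normalized segment-wise (`x/mean − 1`, 1.6 s
  Hann segments, 50% overlap-add with window-weight normalization) and
  projected on \(X_s = 3R_n − 2G_n\), \(Y_s = 1.5R_n + G_n − 1.5B_n\);
  the pulse is \(X_s − (\sigma_{X_s}/\sigma_{Y_s}) Y_s\). The projection
  cancels intensity variations common to all channels (flicker, shading)
  under the standardized-skin-tone assumption.
* **POS**: within a 1.6 s window sliding one sample at a time, the
  mean-normalized channels are projected on \(S_1 = G_n − B_n\) and
  \(S_2 = G_n + B_n − 2R_n\) — a plane orthogonal to the (normalized)
  skin-tone direction — and combined as
  \(h = S_1 + (\sigma_{S_1}/\sigma_{S_2}) S_2\), mean-removed and
  overlap-added. More robust than CHROM when the illumination spectrum
  varies.
* **ICA**: JADE joint-diagonalization of fourth-order cumulants on the
  three conditioned channels. JADE is fully deterministic (eigen-based
  whitening, Jacobi rotations), which is why it is preferred here over
  gradient ICA variants with random restarts.
* **PCA**: eigendecomposition of the 3 × 3 channel covariance.

ICA and PCA return components in arbitrary order and sign, so the
component whose normalized periodogram has the highest single peak
inside the cardiac band is selected (the peak height of the *normalized*
spectrum is scale-invariant, which keeps the rule fair across components
of very different variance). Rank-deficient input — e.g. saturated or
duplicated channels — falls back to the green channel with a warning
rather than failing the run.

Every method's output is re-band-passed and mean-removed, so a
`PulseSignal` is always zero-mean and band-limited regardless of the
technique that produced it.

## Sliding-window Lomb spectral estimation

The Lomb periodogram is a least-squares fit of sinusoids that does not
require uniform sampling; dropped or irregular frames therefore degrade
gracefully (a seeded 10% dropout leaves the peak in place in the test
suite). Windows are 20 s long and slide by 1 s — the standard compromise
between time resolution and spectral stability for resting vital signs;
a duration-\(T\) signal yields \(\lfloor(T − 20)/1\rfloor + 1\)
estimates, i.e. 41 per 60 s analysis span. The frequency grid step is
0.01 Hz (0.6 bpm), finer than any reported agreement statistic; each
rate is \(60 f_{\mathrm{maxPSD}}\). Constant windows (a frozen ROI)
produce a flagged missing value instead of an arbitrary peak.

## Outliers, fusion, SNR selection

Artifact windows produce rate estimates inconsistent with the rest of
the series. Fences are computed once over the whole per-recording series
(not per window): values outside Q1 − 1.5 IQR or Q3 + 1.5 IQR are
replaced by the temporally nearest surviving value, earlier samples
winning ties; quartiles use linear interpolation between order
statistics (R quantile type 7), which makes the worked example
`[70, 71, 72, 73, 200] -> [70, 71, 72, 73, 73]` exactly reproducible.
Because replacing a value can tighten the fences, the screen is repeated
until nothing moves; this makes the operation idempotent by construction
while leaving the first pass — and therefore the worked example —
exactly the single screen described above. Values never flagged keep
their original value.

Three fusion policies mirror the three analysis approaches: per-ROI
series as-is ("single"), the element-wise three-ROI mean ("multi"), and
SNR-based selection, which keeps, per technique, the ROI whose pulse
signal has the highest ratio of spectral energy near the fundamental and
its first harmonic (template half-width 0.1 Hz, evaluated over
0.5–4 Hz) to the energy elsewhere. Selection happens once per recording
— the reading most consistent with picking "the signal" per technique —
and exact ties resolve RCheek, FHead, LCheek. Missing values are filled
by `replaceOutliers()` before fusion so the three-term mean is always
defined.

## Synchronization and agreement

Recordings start with a ~5 s deliberate breath-hold. Its endpoint is
detected on `s_y` as the earliest ≥ `minApneaS` segment whose 1 s moving
SD stays below 10% of the global SD, confirmed by an excursion above 3×
that threshold within 2 s (breathing resumes). Both series are shifted
so the markers coincide, cropped to the analysis span, and the reference
is linearly interpolated onto the estimate's 1 s grid. Agreement is
summarized by the Bland–Altman mean of differences with
LOA = 1.96 × SD (the conventional multiplier), MAE, RMSE and R² taken as
the squared Pearson correlation (the "correlation analysis" reading of
R², not the regression-residual one). Zero-phase filtering throughout
the pipeline exists precisely so this marker is not displaced in time.

# The synthetic scene generator

`renderScene()` builds the ground-truth world every test runs against: a
skin-toned face box whose channels are modulated as
\(\mathrm{base}_c (1 + a_c \sin(2\pi \mathrm{HR}/60\, t))\), plus a
fixed low-contrast skin texture (so spatial averaging and optical flow
both have structure), a slow sinusoidal illumination trend, i.i.d.
Gaussian sensor noise per pixel and channel, and 8-bit quantization; and
a torso band of Gaussian "shirt-fold" stripes translated vertically by
\(A \sin(2\pi f_R/60 (t − t_{\mathrm{apnea}}))\), frozen during the
apnea prefix. Translation is rendered by evaluating the stripe profile
at shifted coordinates — exact subpixel motion, no interpolation error —
and stripe tails stay inside the band so the intensity centroid tracks
the true displacement to < 0.1 px. `renderTraces()` is the trace-level
shortcut producing the same analytic signals without pixels, with the
sensor noise scaled by the face-ROI averaging gain
(\(\sigma/\sqrt{n_{\mathrm{px}}}\)); the pixel/trace equivalence is
itself a tested invariant (agreement within one quantization step), so
properties established on traces transfer to rendered scenes.

Default conditions are the nominal study conditions: 1280 × 720 px at
30 fps, 60 s, ~5 s apnea, HR 72 bpm, fR 15 breaths/min, 2 px chest
excursion, moderate noise (SD 2 counts), slow 2-count illumination
drift. The frame size matters beyond geometry: it sets the ROI pixel
counts and hence the noise-averaging gain of the spatial mean (a 36 px
ROI at 720p averages ~1300 pixels; `renderTraces()` reproduces exactly
that \(\sigma/\sqrt{n_{\mathrm{px}}}\) gain). Rendering actual pixels at
720p is memory-hungry, so pixel-level tests use 160 × 120 px scenes —
trace-level sweeps keep the full-resolution geometry at no cost. The per-channel
pulsatile amplitudes (0.4%, 0.8%, 0.4%) are *not* calibrated to any
specific camera — no published per-channel ratios exist for this setup —
they simply encode "sub-percent modulation, strongest in green", which
is the physiologically expected ordering.

What the generator deliberately does **not** emulate: head motion,
specular reflections, skin-tone diversity, rolling shutter, codec
compression, variable frame rate, multiple people. Passing tests
therefore demonstrate the *algorithmic* correctness of every stage under
the stated signal model, not robustness to motion artifacts or
demographic variation — the two factors flagged as open issues for this
whole family of methods.

# Numerical choices

* **Luminance**: ITU-R BT.601 weights (0.299, 0.587, 0.114); frames are
  held as floating point after conversion, no re-quantization.
* **Horn–Schunck**: \(\alpha = 1\), ≤ 100 iterations with early stop
  when the largest flow update falls below \(10^{-3}\) px/frame — the
  ROI-mean velocity is unchanged versus full convergence at a fraction
  of the cost. Iterations run in compiled code.
* **Integration**: trapezoidal (\(O(\Delta t^2)\)) rather than
  rectangular, at no extra cost.
* **Filters**: Butterworth designs from the `signal` package, applied
  forward–backward; respiratory order 1 (as specified for that band),
  cardiac order 4 (common r-PPG practice; the order is not prescribed).
* **Quantiles**: type 7 (linear interpolation), documented so worked
  examples reproduce bit for bit.
* **Lomb grid**: 0.01 Hz; argmax ties resolve to the lowest frequency
  (`which.max`).
* **Degenerate inputs**: constant spectral windows flag missing values;
  zero-variance CHROM/POS denominators drop the scaled term
  (\(\alpha = 0\)); rank-deficient BSS falls back to green; an
  undetectable apnea yields `NA` and unsynchronized (marker 0)
  evaluation rather than an error mid-pipeline.
* **Problem sizes in the shipped tests**: 60 s trace-level sweeps at
  the full 720p ROI geometry for the HR grid {48, 60, 72, 90, 120, 144}
  bpm × 6 methods; five rendered 160 × 120 px scenes for the fR grid
  {6, 10, 15, 20, 30} breaths/min; a 25 s rendered scene for the
  end-to-end pipeline checks; 10-seed medians at reduced ROI size
  (little averaging gain, so noise actually bites) for the
  noise-degradation ordering; 50 seeded trials for SNR selection. These
  sizes exercise every code path at full sampling rate while keeping
  the suite comfortably reproducible on a laptop.

# Design decisions that were genuinely open

* ROIs are placed once, on the first frame, and never re-tracked — the
  protocol frames a still, seated subject, and fixed ROIs make runs
  exactly reproducible.
* The torso ROI is derived geometrically from the face box (width equal
  to the face box, top edge 25% of the face height below it) rather
  than re-detecting the pit of the neck; no landmark algorithm beyond
  face detection is assumed.
* Face detection is a skin-chromaticity blob detector (largest plausible
  connected component), with a manual ROI override that bypasses
  detection entirely — the override, not the detector, is the contract
  the rest of the pipeline depends on.
* Exact cheek/forehead offsets inside the face box (20%/60% heights,
  ±25% width) place the squares over well-vascularized frontal skin;
  all fractions are arguments, not constants.
* CHROM/POS internals (projection axes, 1.6 s windows, Hann overlap-add)
  follow their original method descriptions, since the technique names
  delegate the mathematics to those sources.
* The multi-ROI mean is computed after per-ROI outlier replacement, so
  one artifact-laden ROI cannot poison the fused series — the fused
  series is never worse than the worst single ROI (asserted under a
  corrupted-ROI test).

# Known limitations

Motion artifacts are not compensated; the method degrades with distance
and dim light (reproduced qualitatively as the noise-degradation
ordering in the test suite); HR during apnea relies on pulse modulation
alone (by design — that is what makes the apnea visible in `s_y` but not
in the r-PPG); beat-to-beat intervals and HRV indices are out of scope;
and video containers must be demuxed to frame directories before
ingestion, since no codec stack is bundled.
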