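#' @include AllClasses.R
NULL

# Centered moving standard deviation with a window of `w` samples,
# shrunk near the edges.
movingSd <- function(x, w) {
  n <- length(x)
  half <- max(1L, floor(w / 2))
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    sd(x[idx])
  }, numeric(1L))
}

#' Detect the apnea endpoint in a respiratory trace
#'
#' The recording protocol starts with a deliberate breath-hold; its
#' endpoint is the synchronization marker between the video-derived trace
#' and the reference recording. The detector finds the earliest segment of
#' at least `minApneaS` seconds during which the 1-s moving standard
#' deviation of s_y stays below 10% of the trace's global SD, and requires
#' an excursion above 3x that threshold within 2 s after the segment ends
#' (breathing resumes). Returns the segment end time.
#'
#' @param trace a [DisplacementTrace-class].
#' @param minApneaS minimum apnea length (s).
#' @return Apnea end time (s).
#' @export
detectApneaEndpoint <- function(trace, minApneaS = 3) {
  stopifnot(is(trace, "DisplacementTrace"))
  t <- trace@t; x <- trace@sy
  fs <- 1 / median(diff(t))
  if (length(x) < (minApneaS + 5) * fs)
    stop("trace too short: need at least minApneaS + 5 seconds")
  ms <- movingSd(x, round(fs))
  thr <- 0.1 * sd(x)
  if (!is.finite(thr) || thr <= 0)
    stop("detection error: flat trace, no apnea endpoint; ",
         "supply a manual marker")
  quiet <- ms < thr
  runs <- rle(quiet)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  minLen <- round(minApneaS * fs)
  horizon <- round(2 * fs)
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k] || runs$lengths[k] < minLen) next
    e <- ends[k]
    after <- ms[e:min(length(ms), e + horizon)]
    if (any(after > 3 * thr)) return(t[e])
  }
  stop("detection error: no qualifying apnea segment; ",
       "supply a manual marker")
}

#' Align an estimate and a reference at their synchronization markers
#'
#' Shifts both series so their markers (typically apnea endpoints)
#' coincide at t = 0, crops both to the analysis span, and resamples the
#' reference onto the estimate's time base by linear interpolation.
#'
#' @param est,ref [RateSeries-class] objects, or lists/data.frames with
#'   elements `t` and a value vector (`rate` or `value`).
#' @param estMarker,refMarker marker times (s) on each series' own clock.
#' @param analysisS analysis span after the marker (s); 60 s by default.
#' @return data.frame with columns `t`, `est`, `ref`.
#' @export
alignAndCrop <- function(est, ref, estMarker = 0, refMarker = 0,
                         analysisS = 60) {
  pick <- function(s) {
    if (is(s, "RateSeries")) list(t = s@t, v = s@rate)
    else {
      v <- if (!is.null(s$rate)) s$rate else s$value
      list(t = s$t, v = v)
    }
  }
  e <- pick(est); r <- pick(ref)
  te <- e$t - estMarker
  tr <- r$t - refMarker
  keep <- te >= 0 & te <= analysisS
  if (!any(keep))
    stop("estimate does not cover [marker, marker + analysisS]")
  te <- te[keep]; ev <- e$v[keep]
  if (min(tr) > min(te) + 1e-9 || max(tr) < max(te) - 1e-9)
    stop("reference does not cover the cropped analysis span")
  rv <- approx(tr, r$v, xout = te)$y
  data.frame(t = te, est = ev, ref = rv)
}

#' Bland-Altman statistics
#'
#' Mean of differences (MOD) and half-width of the 95% limits of
#' agreement: 1.96 x the sample SD (n - 1) of the differences
#' d = est - ref.
#'
#' @param est,ref numeric vectors of equal length (>= 2).
#' @return Named vector `c(mod, loaHalfWidth)`.
#' @examples
#' blandAltman(c(71, 72, 73), c(72, 72, 72)) # mod 0, loa 1.96
#' @export
blandAltman <- function(est, ref) {
  if (length(est) != length(ref)) stop("length mismatch")
  stopifnot(length(est) >= 2L)
  d <- est - ref
  c(mod = mean(d), loaHalfWidth = 1.96 * sd(d))
}

#' Error metrics between estimate and reference
#'
#' Mean absolute error, root-mean-square error and the coefficient of
#' determination taken as the squared Pearson correlation.
#'
#' @param est,ref numeric vectors of equal length (>= 2).
#' @return Named vector `c(mae, rmse, r2)`; r2 is NA when the reference
#'   has no variance.
#' @export
errorMetrics <- function(est, ref) {
  if (length(est) != length(ref)) stop("length mismatch")
  stopifnot(length(est) >= 2L)
  d <- est - ref
  r2 <- if (var(ref) > 0 && var(est) > 0) cor(est, ref)^2 else NA_real_
  c(mae = mean(abs(d)), rmse = sqrt(mean(d^2)), r2 = r2)
}

#' Full agreement report between an estimated and a reference series
#'
#' Convenience wrapper combining [blandAltman()] and [errorMetrics()]
#' into an [AgreementReport-class].
#'
#' @param est,ref numeric vectors (already aligned, equal length).
#' @return An [AgreementReport-class].
#' @export
agreementReport <- function(est, ref) {
  ba <- blandAltman(est, ref)
  em <- errorMetrics(est, ref)
  new("AgreementReport", mod = unname(ba["mod"]),
      loaHalfWidth = unname(ba["loaHalfWidth"]), mae = unname(em["mae"]),
      rmse = unname(em["rmse"]), r2 = unname(em["r2"]),
      n = length(est))
}

#' Read a reference rate or waveform CSV
#'
#' Accepts either a rate series (`time_s, rate`) or a raw waveform
#' (`time_s, value`); a waveform is converted to a rate series on the fly
#' with the same sliding-window spectral settings used for the video
#' signals.
#'
#' @param path CSV file.
#' @param cfg a [SpectralConfig-class] used for waveform conversion.
#' @return A [RateSeries-class] (source `"reference"`).
#' @export
readReference <- function(path, cfg = spectralConfig()) {
  df <- read.csv(path)
  if ("rate" %in% names(df))
    return(rateSeries(df$time_s, df$rate, source = "reference"))
  if (!"value" %in% names(df))
    stop("reference CSV needs columns time_s,rate or time_s,value")
  slidingRates(df$value, cfg, t = df$time_s, source = "reference")
}
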