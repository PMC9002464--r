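#' @include AllClasses.R synthgen.R video_io.R roi_detect.R respiration.R
#' @include rppg_methods.R rate_estimation.R evaluation.R
NULL

#' Assemble a pipeline run configuration
#'
#' Collects every tunable of an end-to-end run; the defaults mirror the
#' standard analysis settings (20 s / 1 s Lomb windows, 0.5-2.5 Hz cardiac
#' and 0.05-2 Hz respiratory bands, SPA lambda 60, Horn-Schunck alpha 1
#' with 100 iterations). A fixed seed makes the run fully reproducible.
#'
#' @param roiMode `"auto"` (face detection) or a path to a manual ROI CSV.
#' @param distanceMode `"near"` (0.5 m; face ROI side 5% of frame height)
#'   or `"far"` (1 m; 3%).
#' @param methods subset of Green, MODW, CHROM, POS, ICA, PCA.
#' @param fusion `"single"`, `"multi"` or `"snr"`.
#' @param spectralHr,spectralFr [SpectralConfig-class] for the cardiac and
#'   respiratory analyses.
#' @param lambda SPA detrending parameter.
#' @param hsAlpha,hsIter Horn-Schunck smoothness weight and iterations.
#' @param minApneaS minimum apnea length for synchronization (s).
#' @param analysisS analysis span after synchronization (s).
#' @param seed RNG seed recorded with the run.
#' @param outDir output directory, or NULL for no file output.
#' @param referenceHr,referenceFr optional reference CSV paths
#'   (see [readReference()]).
#' @return A `pulsecamConfig` list.
#' @export
pipelineConfig <- function(roiMode = "auto",
                           distanceMode = c("near", "far"),
                           methods = RPPG_METHODS,
                           fusion = c("multi", "single", "snr"),
                           spectralHr = spectralConfig(band = CARDIAC_BAND),
                           spectralFr = spectralConfig(
                             band = RESPIRATORY_BAND),
                           lambda = 60, hsAlpha = 1, hsIter = 100,
                           minApneaS = 3, analysisS = 60, seed = 1L,
                           outDir = NULL, referenceHr = NULL,
                           referenceFr = NULL) {
  distanceMode <- match.arg(distanceMode)
  fusion <- match.arg(fusion)
  if (length(methods) < 1L || !all(methods %in% RPPG_METHODS))
    stop("config error: methods must be a non-empty subset of ",
         paste(RPPG_METHODS, collapse = ", "))
  structure(list(roiMode = roiMode, distanceMode = distanceMode,
                 methods = methods, fusion = fusion,
                 spectralHr = spectralHr, spectralFr = spectralFr,
                 lambda = lambda, hsAlpha = hsAlpha, hsIter = hsIter,
                 minApneaS = minApneaS, analysisS = analysisS,
                 seed = as.integer(seed), outDir = outDir,
                 referenceHr = referenceHr, referenceFr = referenceFr),
            class = "pulsecamConfig")
}

applyMethod <- function(method, trace, lambda = 60) {
  switch(method,
         Green = methodGreen(trace, lambda),
         MODW = methodModwt(trace, lambda),
         CHROM = methodChrom(trace, lambda),
         POS = methodPos(trace, lambda),
         ICA = methodBss(trace, "ICA", lambda),
         PCA = methodBss(trace, "PCA", lambda),
         stop("unknown method '", method, "'"))
}

writeRateCsv <- function(rs, path) {
  write.csv(data.frame(time_s = rs@t, rate = rs@rate,
                       outlier_flag = rs@outlier, source = rs@source),
            path, row.names = FALSE)
  invisible(path)
}

#' Run the full video-to-vitals pipeline
#'
#' Orchestrates every stage: frame ingestion, ROI layout (automatic face
#' detection or a manual CSV), Horn-Schunck respiration extraction and
#' per-second fR estimation, per-ROI r-PPG extraction through the
#' requested techniques, per-second HR estimation with outlier
#' replacement, and single-ROI / multi-ROI / SNR-based fusion. When
#' reference CSVs are supplied, series are synchronized at the detected
#' apnea endpoint and agreement statistics are computed. With `outDir`
#' set, all signals and rate series are written as CSV together with a
#' `run_log.yaml` recording every parameter actually used.
#'
#' @param input a [FrameSequence-class], a frame directory path, or the
#'   list returned by [renderScene()].
#' @param cfg a [pipelineConfig()] list.
#' @return A list bundle: `rois`, `sy` (displacement trace), `fr`
#'   (respiratory [RateSeries-class]), `pulses` (per ROI, per method),
#'   `hrSingle` (per ROI, per method), `hr` (fused, per method),
#'   `apneaEnd` (time or NA), and `agreement` (per-method HR and fR
#'   [AgreementReport-class]s when references were given).
#' @export
runPipeline <- function(input, cfg = pipelineConfig()) {
  stopifnot(inherits(cfg, "pulsecamConfig"))
  set.seed(cfg$seed)
  seq <- if (is(input, "FrameSequence")) input
         else if (is.list(input) && is(input$frames, "FrameSequence"))
           input$frames
         else loadFrames(input)

  rois <- if (identical(cfg$roiMode, "auto")) {
    face <- detectFace(getFrame(seq, 1L))
    placeRois(face, frameSize(seq), mode = cfg$distanceMode)
  } else readRoiCsv(cfg$roiMode)

  sy <- extractRespiration(seq, getRoi(rois, "Torso"),
                           alpha = cfg$hsAlpha, nIter = cfg$hsIter)
  fr <- replaceOutliers(slidingRates(sy, cfg$spectralFr))
  apneaEnd <- tryCatch(detectApneaEndpoint(sy, cfg$minApneaS),
                       error = function(e) NA_real_)

  pulses <- list(); hrSingle <- list(); hrFused <- list()
  traces <- lapply(FACE_ROI_LABELS, function(lab)
    extractRgbTrace(seq, getRoi(rois, lab)))
  names(traces) <- FACE_ROI_LABELS
  for (m in cfg$methods) {
    pulses[[m]] <- lapply(traces, applyMethod, method = m,
                          lambda = cfg$lambda)
    hrSingle[[m]] <- lapply(pulses[[m]], function(p)
      replaceOutliers(slidingRates(p, cfg$spectralHr)))
    hrFused[[m]] <- switch(cfg$fusion,
      multi = fuseMultiRoi(hrSingle[[m]]$LCheek, hrSingle[[m]]$FHead,
                           hrSingle[[m]]$RCheek),
      snr = {
        best <- selectBySnr(pulses[[m]])
        rs <- replaceOutliers(slidingRates(best, cfg$spectralHr))
        rateSeries(rs@t, rs@rate, rs@outlier,
                   source = paste0("snr:", best@roiLabel))
      },
      single = hrSingle[[m]][["RCheek"]])
  }

  agreement <- NULL
  if (!is.null(cfg$referenceHr) || !is.null(cfg$referenceFr)) {
    agreement <- list()
    marker <- if (is.na(apneaEnd)) 0 else apneaEnd
    span <- cfg$analysisS
    if (!is.null(cfg$referenceFr)) {
      refFr <- readReference(cfg$referenceFr, cfg$spectralFr)
      al <- alignAndCrop(fr, refFr, marker, 0, span)
      agreement$fr <- agreementReport(al$est, al$ref)
    }
    if (!is.null(cfg$referenceHr)) {
      refHr <- readReference(cfg$referenceHr, cfg$spectralHr)
      agreement$hr <- lapply(hrFused, function(rs) {
        al <- alignAndCrop(rs, refHr, marker, 0, span)
        agreementReport(al$est, al$ref)
      })
    }
  }

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    writeRoiCsv(rois, file.path(cfg$outDir, "rois.csv"))
    write.csv(data.frame(time_s = sy@t, s_y = sy@sy),
              file.path(cfg$outDir, "sy.csv"), row.names = FALSE)
    writeRateCsv(fr, file.path(cfg$outDir, "fr.csv"))
    for (m in names(pulses)) {
      for (lab in names(pulses[[m]])) {
        p <- pulses[[m]][[lab]]
        write.csv(data.frame(time_s = p@t, value = p@value, method = m,
                             roi = lab),
                  file.path(cfg$outDir,
                            sprintf("pulse_%s_%s.csv", m, lab)),
                  row.names = FALSE)
        writeRateCsv(hrSingle[[m]][[lab]],
                     file.path(cfg$outDir,
                               sprintf("hr_%s_%s.csv", m, lab)))
      }
      writeRateCsv(hrFused[[m]],
                   file.path(cfg$outDir,
                             sprintf("hr_%s_%s.csv", m, cfg$fusion)))
    }
    if (!is.null(agreement)) {
      toList <- function(a) list(mod = a@mod,
                                 loa_half_width = a@loaHalfWidth,
                                 mae = a@mae, rmse = a@rmse, r2 = a@r2,
                                 n = a@n)
      rep <- list()
      if (!is.null(agreement$fr)) rep$fr <- toList(agreement$fr)
      if (!is.null(agreement$hr))
        rep$hr <- lapply(agreement$hr, toList)
      jsonlite::write_json(rep, file.path(cfg$outDir, "agreement.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    log <- list(
      roi_mode = cfg$roiMode, distance_mode = cfg$distanceMode,
      methods = cfg$methods, fusion = cfg$fusion,
      spectral_hr = list(window_s = cfg$spectralHr@windowS,
                         step_s = cfg$spectralHr@stepS,
                         grid_hz = cfg$spectralHr@gridHz,
                         band = cfg$spectralHr@band),
      spectral_fr = list(window_s = cfg$spectralFr@windowS,
                         step_s = cfg$spectralFr@stepS,
                         grid_hz = cfg$spectralFr@gridHz,
                         band = cfg$spectralFr@band),
      spa_lambda = cfg$lambda, hs_alpha = cfg$hsAlpha,
      hs_iterations = cfg$hsIter, seed = cfg$seed,
      apnea_end_s = if (is.na(apneaEnd)) "none" else apneaEnd,
      rois = lapply(seq_len(nrow(rois@rois)), function(i)
        as.list(rois@rois[i, ])))
    yaml::write_yaml(log, file.path(cfg$outDir, "run_log.yaml"))
  }

  list(rois = rois, sy = sy, fr = fr, pulses = pulses,
       hrSingle = hrSingle, hr = hrFused, apneaEnd = apneaEnd,
       agreement = agreement)
}
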