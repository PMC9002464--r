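#' @include AllClasses.R
NULL

#' Detect the dominant face in a frame
#'
#' Locates the subject's face in the first video frame from a skin
#' chromaticity mask: pixels whose channel ordering and spacing match skin
#' (R > G > B with margins, adequate brightness) are labelled into
#' connected components and the largest plausible component's bounding box
#' is returned. When several face-sized components are present the largest
#' area wins (the subject is the dominant face in frame). For recordings
#' where the mask fails (heavy make-up, unusual lighting), supply ROIs
#' manually via [readRoiCsv()] / [roiSet()] instead.
#'
#' @param frame an H x W x 3 intensity array (counts, 0-255), typically
#'   `getFrame(seq, 1)`.
#' @param minHeight smallest acceptable face-box height (px).
#' @return 0-based named vector `c(x0, y0, width, height)`.
#' @export
detectFace <- function(frame, minHeight = 40) {
  stopifnot(length(dim(frame)) == 3L, dim(frame)[3L] == 3L)
  R <- frame[, , 1L]; G <- frame[, , 2L]; B <- frame[, , 3L]
  mask <- (R > G + 10) & (G > B + 5) & (R > 85) & (R < 256)
  if (!any(mask))
    stop("detection error: no face found; supply manual ROI coordinates")
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  best <- NULL; bestArea <- 0
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    h <- diff(range(idx[, 1L])) + 1L
    w <- diff(range(idx[, 2L])) + 1L
    area <- nrow(idx)
    # reject thin slivers and non-face-sized blobs
    if (h < minHeight / 2 || w < 4 || area < 0.4 * h * w) next
    if (area > bestArea) {
      bestArea <- area
      best <- c(x0 = min(idx[, 2L]) - 1L, y0 = min(idx[, 1L]) - 1L,
                width = w, height = h)
    }
  }
  if (is.null(best) || best["height"] < minHeight / 2)
    stop("detection error: no face found; supply manual ROI coordinates")
  best
}

#' Lay out the four analysis ROIs from a face box
#'
#' Places the three square facial ROIs over well-vascularized skin of a
#' frontal face box -- the forehead centred at 20% of the box height, the
#' cheeks at 60% height offset by +/-25% of the box width from the face
#' centre -- and a torso rectangle of the face-box width, half its height,
#' whose top edge sits 25% of the face height below the box. Face ROIs are
#' square with side equal to 5% of the frame height in `near` mode (0.5 m
#' recordings) or 3% in `far` mode (1 m). ROIs are computed once, on the
#' first frame, and reused for all frames. Rectangles falling outside the
#' frame are clipped; a clip below the 4 px minimum is a placement error.
#'
#' @param faceBox 0-based `c(x0, y0, width, height)` from [detectFace()]
#'   or supplied manually.
#' @param frameSize integer (width, height) of the frame in pixels.
#' @param mode `"near"` (5% of frame height) or `"far"` (3%).
#' @param fheadY,cheekY vertical centres of forehead and cheek ROIs as
#'   fractions of the face-box height.
#' @param cheekDx horizontal cheek offset as a fraction of face-box width.
#' @param torsoGap gap between face bottom and torso top as a fraction of
#'   face-box height.
#' @param torsoHeight torso ROI height as a fraction of face-box height.
#' @return A [RoiSet-class] with source `"auto"`.
#' @examples
#' placeRois(c(400, 100, 200, 200), frameSize = c(1280, 720), mode = "near")
#' @export
placeRois <- function(faceBox, frameSize, mode = c("near", "far"),
                      fheadY = 0.2, cheekY = 0.6, cheekDx = 0.25,
                      torsoGap = 0.25, torsoHeight = 0.5) {
  mode <- match.arg(mode)
  fb <- as.numeric(faceBox)
  if (length(fb) != 4L || fb[3L] <= 0 || fb[4L] <= 0)
    stop("faceBox must be c(x0, y0, width, height) with positive size")
  W <- frameSize[1L]; H <- frameSize[2L]
  side <- round(if (mode == "near") 0.05 * H else 0.03 * H)
  cx <- fb[1L] + fb[3L] / 2

  clip <- function(x0, y0, w, h, label) {
    x1 <- min(x0 + w, W); y1 <- min(y0 + h, H)
    x0 <- max(x0, 0); y0 <- max(y0, 0)
    w <- x1 - x0; h <- y1 - y0
    if (w < 4 || h < 4)
      stop("placement error: ROI '", label,
           "' smaller than 4 px after clipping to the frame")
    data.frame(label = label, x0 = round(x0), y0 = round(y0),
               width = round(w), height = round(h))
  }
  square <- function(cx, cy, label)
    clip(round(cx - side / 2), round(cy - side / 2), side, side, label)

  rois <- rbind(
    square(cx - cheekDx * fb[3L], fb[2L] + cheekY * fb[4L], "LCheek"),
    square(cx, fb[2L] + fheadY * fb[4L], "FHead"),
    square(cx + cheekDx * fb[3L], fb[2L] + cheekY * fb[4L], "RCheek"),
    clip(fb[1L], fb[2L] + fb[4L] + torsoGap * fb[4L], fb[3L],
         torsoHeight * fb[4L], "Torso"))
  roiSet(rois, source = "auto")
}

#' Read and write ROI coordinate files
#'
#' ROI files are CSV with columns `label,x0,y0,width,height`: 0-based
#' pixel coordinates, top-left origin, end-exclusive extents.
#'
#' @param path CSV file path.
#' @return `readRoiCsv` returns a [RoiSet-class] with source `"manual"`.
#' @export
readRoiCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  roiSet(df, source = "manual")
}

#' @rdname readRoiCsv
#' @param rs a [RoiSet-class] to write.
#' @return `writeRoiCsv` returns `path`, invisibly.
#' @export
writeRoiCsv <- function(rs, path) {
  stopifnot(is(rs, "RoiSet"))
  write.csv(rs@rois, path, row.names = FALSE)
  invisible(path)
}

# 1-based row/column index ranges of a ROI rectangle (one-row data.frame).
roiRows <- function(r) (r$y0 + 1L):(r$y0 + r$height)
roiCols <- function(r) (r$x0 + 1L):(r$x0 + r$width)
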