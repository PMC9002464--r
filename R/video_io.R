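#' @include AllClasses.R
NULL

#' Load a frame sequence from a directory of image frames
#'
#' Reads an ordered directory of equally sized PNG or TIFF frames (the
#' interchange format written by [writeScene()]; files are taken in
#' lexicographic order, so zero-padded numeric names preserve temporal
#' order). Intensities are returned on the 0-255 count scale. No video
#' container decoder is bundled: demux a container into numbered frames
#' with an external tool first.
#'
#' @param path directory holding the frames.
#' @param frameRate frames per second. Read from a `config.yaml` sidecar
#'   when present; an explicit value overrides the sidecar. When neither is
#'   available an error is raised.
#' @return A [FrameSequence-class].
#' @examples
#' d <- tempfile()
#' writeScene(renderScene(sceneConfig(duration = 1, frameSize = c(96, 72),
#'                                    apneaDuration = 0)), d)
#' loadFrames(d)
#' @export
loadFrames <- function(path, frameRate = NULL) {
  if (!dir.exists(path))
    stop("I/O error: '", path, "' is not a readable directory")
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop("I/O error: no PNG/TIFF frames found in '", path, "'")
  if (is.null(frameRate)) {
    sidecar <- file.path(path, "config.yaml")
    if (file.exists(sidecar)) {
      cfg <- yaml::read_yaml(sidecar)
      frameRate <- cfg$frame_rate
    }
  }
  if (is.null(frameRate))
    stop("frameRate not given and no config.yaml sidecar found")

  readOne <- function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE] # drop alpha
    round(img * 255)
  }
  first <- readOne(files[1L])
  d <- dim(first)
  frames <- array(0L, dim = c(d[1L], d[2L], d[3L], length(files)))
  frames[, , , 1L] <- as.integer(first)
  if (length(files) > 1L) for (i in 2:length(files)) {
    img <- readOne(files[i])
    if (!identical(dim(img), d))
      stop("format error: frame '", basename(files[i]),
           "' has a different size than the first frame")
    frames[, , , i] <- as.integer(img)
  }
  frameSequence(frames, frameRate,
                colorMode = if (d[3L] == 3L) "rgb" else "grey")
}

#' Convert an RGB frame sequence to greyscale
#'
#' Applies the ITU-R BT.601 luminance map
#' \eqn{Y = 0.299 R + 0.587 G + 0.114 B} per pixel, keeping the result at
#' floating precision (no re-quantization), as required before optical-flow
#' computation. A sequence that is already greyscale is returned unchanged.
#'
#' @param seq a [FrameSequence-class].
#' @return A greyscale [FrameSequence-class].
#' @export
toGreyscale <- function(seq) {
  stopifnot(is(seq, "FrameSequence"))
  if (seq@colorMode == "grey") return(seq)
  g <- 0.299 * seq@frames[, , 1L, , drop = FALSE] +
       0.587 * seq@frames[, , 2L, , drop = FALSE] +
       0.114 * seq@frames[, , 3L, , drop = FALSE]
  frameSequence(g, seq@frameRate, "grey")
}
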