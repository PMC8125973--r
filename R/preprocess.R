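#' Centered moving-average smoothing with edge replication
#'
#' @param series numeric vector.
#' @param window odd positive integer window in frames; 1 returns the input
#'   unchanged.
#' @return numeric vector, same length as the input.
#' @export
#' @examples
#' smooth_series(c(0, 0, 1, 0, 0), 3)
smooth_series <- function(series, window = 5) {
  x <- as.numeric(series)
  if (length(x) < 1) stop_arg("empty series")
  if (!is.numeric(window) || window < 1 || window %% 2 == 0)
    stop_arg("window must be an odd positive integer, got %s",
             deparse(window))
  if (window == 1) return(x)
  h <- (window - 1) / 2
  padded <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(padded, rep(1 / window, window),
                           sides = 2))[(h + 1):(h + length(x))]
}

#' Select the key frames of a sample video
#'
#' Picks one frame per requested second: the frame at the midpoint of that
#' second, index `floor((s + 0.5) * fps)` (1-based). The defaults (seconds 1,
#' 3 and 4) bracket the facial response to a phasic stimulus whose plateau
#' begins at second 1 and whose facial activity rises about two seconds
#' later.
#'
#' @param frames list of frames (grayscale matrices or H x W x 3 arrays), in
#'   temporal order.
#' @param fps frames per second of the video.
#' @param seconds integer seconds to sample (default `c(1, 3, 4)`).
#' @return list of `length(seconds)` frames.
#' @export
select_frames <- function(frames, fps, seconds = c(1, 3, 4)) {
  if (!length(frames)) stop_arg("no frames supplied")
  if (fps <= 0) stop_arg("fps must be positive")
  dur <- length(frames) / fps
  if (dur < max(seconds) + 1)
    stop_arg("video spans %.2f s but seconds up to %d were requested",
             dur, max(seconds))
  idx <- pmax(1L, as.integer(floor((seconds + 0.5) * fps)))
  frames[idx]
}

#' Indices chosen by [select_frames()]
#' @inheritParams select_frames
#' @param n_frames number of frames in the video.
#' @return integer frame indices (1-based).
#' @export
frame_indices <- function(n_frames, fps, seconds = c(1, 3, 4)) {
  if (n_frames / fps < max(seconds) + 1)
    stop_arg("video spans %.2f s but seconds up to %d were requested",
             n_frames / fps, max(seconds))
  pmax(1L, as.integer(floor((seconds + 0.5) * fps)))
}

to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3 && dim(img)[3] >= 3)
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  if (length(dim(img)) == 3 && dim(img)[3] == 1) return(img[, , 1])
  stop_arg("frame must be a matrix or an H x W x C array")
}

resize_gray <- function(img, side) {
  if (all(dim(img) == c(side, side))) return(img)
  m <- EBImage::imageData(EBImage::resize(EBImage::Image(img), w = side,
                                          h = side))
  array(as.numeric(m), dim = c(side, side))
}

#' Encode three frames as a spatio-temporal RGB image
#'
#' Converts each of the three frames to grayscale (Rec. 601 luma weights),
#' resizes them to a common square side with bilinear interpolation, and
#' stacks them as the red, green and blue channels in temporal order. The
#' earliest frame becomes the red channel. Pixel values are clipped to
#' `[0, 1]`. Color in the result therefore encodes facial movement between
#' the three points in time.
#'
#' @param frames3 list of exactly 3 frames (grayscale matrices or RGB
#'   arrays), earliest first.
#' @param side output side length in pixels (default 96).
#' @return `side x side x 3` numeric array in `[0, 1]`.
#' @export
encode_spatiotemporal <- function(frames3, side = 96) {
  if (!is.list(frames3) || length(frames3) != 3)
    stop_arg("encode_spatiotemporal() expects a list of exactly 3 frames")
  chans <- lapply(frames3, function(f) resize_gray(to_gray(f), side))
  out <- array(0, dim = c(side, side, 3))
  for (i in 1:3) out[, , i] <- pmin(pmax(chans[[i]], 0), 1)
  out
}

#' Constant prediction image encoding a class index
#'
#' Encodes a classifier's hard 7-class prediction (0-6, in [class_codes()]
#' order) as a constant single-channel image of value `index / 6`, used as
#' the second branch input of the fusion networks. [decode_prediction()]
#' inverts the encoding exactly for all 7 classes.
#'
#' @param class_index integer 0-6.
#' @param side image side (default 28).
#' @return `side x side x 1` array with all pixels equal to `class_index/6`.
#' @export
#' @examples
#' decode_prediction(encode_prediction(3))
encode_prediction <- function(class_index, side = 28) {
  if (length(class_index) != 1 || is.na(class_index) ||
      class_index != as.integer(class_index) ||
      class_index < 0 || class_index > 6)
    stop_arg("class_index must be a single integer in 0..6")
  array(class_index / 6, dim = c(side, side, 1))
}

#' @rdname encode_prediction
#' @param img a prediction image produced by [encode_prediction()].
#' @return `decode_prediction()` returns the integer class index 0-6.
#' @export
decode_prediction <- function(img) {
  v <- round(mean(img) * 6)
  if (v < 0 || v > 6) stop_arg("image does not encode a class in 0..6")
  as.integer(v)
}

#' Spatio-temporal input image for one sample
#'
#' Convenience wrapper: obtains the sample's frames at seconds 1, 3 and 4
#' (reading PNG frames from disk when the sample references a frame
#' directory, otherwise rendering them from the AU series with
#' [render_frames()]) and encodes them with [encode_spatiotemporal()].
#'
#' @param sample an `au_sample`.
#' @param side output side in pixels.
#' @param render_size side at which schematic frames are rendered (default
#'   `max(side, 32)`).
#' @param seconds seconds to sample, passed to [select_frames()].
#' @return `side x side x 3` array.
#' @export
sample_spatiotemporal <- function(sample, side = 96, render_size = NULL,
                                  seconds = c(1, 3, 4)) {
  n_frames <- ncol(sample$series)
  idx <- frame_indices(n_frames, sample$fps, seconds)
  frames <- if (!is.null(sample$frames_dir) && !is.na(sample$frames_dir) &&
                nzchar(sample$frames_dir)) {
    files <- file.path(sample$frames_dir, sprintf("frame_%04d.png", idx))
    lapply(files, png::readPNG)
  } else {
    render_size <- render_size %||% max(side, 32)
    lapply(idx, function(i) render_frame(sample, i, size = render_size))
  }
  encode_spatiotemporal(frames, side = side)
}
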