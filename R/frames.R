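#' Validate a frame
#'
#' A frame is either a numeric matrix (grayscale) or a numeric
#' `height x width x 3` array (RGB), with intensities on the 0..255 scale.
#'
#' @param frame matrix or 3-d array of intensities in `[0, 255]`.
#' @return the frame, invisibly, after validation.
#' @keywords internal
check_frame <- function(frame) {
  if (is.null(frame) || !(is.matrix(frame) || (is.array(frame) && length(dim(frame)) == 3L)))
    stop("frame must be a numeric matrix or a h x w x 3 array", call. = FALSE)
  d <- dim(frame)
  if (d[1] == 0L || d[2] == 0L)
    stop("frame has zero area", call. = FALSE)
  if (length(d) == 3L && d[3] != 3L)
    stop("color frames must have exactly 3 planes", call. = FALSE)
  if (!is.numeric(frame))
    stop("frame intensities must be numeric", call. = FALSE)
  invisible(frame)
}

#' Convert a frame to grayscale
#'
#' Color frames are reduced with the ITU-R BT.601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale frames pass through unchanged.
#'
#' @param frame matrix or `h x w x 3` array, intensities 0..255.
#' @return numeric matrix of luminance values.
#' @export
as_gray <- function(frame) {
  check_frame(frame)
  if (is.matrix(frame)) return(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

#' Read a frame from a PNG file
#'
#' @param path path to a PNG image.
#' @return a frame (matrix for grayscale input, `h x w x 3` array for color),
#'   intensities rescaled to 0..255.
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) img <- img[, , 1:3] else img <- img[, , 1]
  }
  img * 255
}

#' Write a frame to a PNG file
#'
#' @param frame frame on the 0..255 scale; values are clamped to that range.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  check_frame(frame)
  png::writePNG(pmin(pmax(frame / 255, 0), 1), path)
  invisible(path)
}

#' Open a frame source
#'
#' Normalizes the two supported inputs - an in-memory list of frames or a
#' directory of PNG stills (read in lexicographic filename order) - into a
#' list with `n` (frame count) and `get(i)` (1-based accessor).
#'
#' @param x list of frames, or path to a directory containing `*.png`.
#' @return a frame source (list with fields `n` and `get`).
#' @export
frame_source <- function(x) {
  if (is.list(x) && !is.null(x$get) && !is.null(x$n)) return(x)
  if (is.list(x)) {
    lapply(x, check_frame)
    return(list(n = length(x), get = function(i) x[[i]]))
  }
  if (is.character(x) && length(x) == 1L) {
    if (!dir.exists(x)) stop("frame directory not found: ", x, call. = FALSE)
    files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG frames in ", x, call. = FALSE)
    return(list(n = length(files), get = function(i) read_frame_png(files[i])))
  }
  stop("unsupported frame source; supply a list of frames or a PNG directory",
       call. = FALSE)
}
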