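# Stateless per-frame computations: sharpness, blur decision, perceptual
# hashing, hash distance and speed-zone categorization.

#' Variance of the Laplacian response
#'
#' Sharpness score used for blur detection: the image is convolved with the
#' 3x3 4-neighbour discrete Laplacian (centre -4), and the variance of the
#' response over all pixels is returned. Low values indicate defocus or
#' motion blur. Color frames are first converted to luminance with
#' [as_gray()]; image borders are handled by edge replication.
#'
#' @param frame frame (matrix or `h x w x 3` array), intensities 0..255.
#' @return non-negative scalar, the Laplacian-response variance (intensity^2).
#' @examples
#' laplacian_variance(matrix(128, 16, 16)) # constant image -> 0
#' @export
laplacian_variance <- function(frame) {
  g <- as_gray(frame)
  h <- nrow(g); w <- ncol(g)
  # edge-replicated neighbours
  up    <- g[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down  <- g[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  left  <- g[, c(1L, seq_len(w - 1L)), drop = FALSE]
  right <- g[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  lap <- up + down + left + right - 4 * g
  n <- length(lap)
  if (n < 2L) return(0)
  stats::var(as.vector(lap)) * (n - 1) / n  # population variance
}

#' Blur decision
#'
#' A frame is classified as blurred when its Laplacian-response variance
#' falls strictly below the threshold. The default threshold of 50 is
#' calibrated for 8-bit frames at roughly standard-definition resolution
#' and is exposed as a configuration knob.
#'
#' @param variance non-negative Laplacian variance.
#' @param threshold positive decision threshold (same units), default 50.
#' @return logical: `TRUE` iff `variance < threshold`.
#' @export
is_blurred <- function(variance, threshold = 50) {
  if (!is.numeric(variance) || length(variance) != 1L || is.na(variance) || variance < 0)
    stop("variance must be a single non-negative number", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number", call. = FALSE)
  variance < threshold
}

# 8 x 32 slice of the (unnormalized) DCT-II basis used by the perceptual hash
.dct_rows8 <- local({
  k <- 0:31
  outer(0:7, k, function(u, x) 2 * cos(pi * (2 * x + 1) * u / 64))
})

# area-average (block mean) resize of a matrix to `out` x `out`
.area_resize <- function(m, out = 32L) {
  h <- nrow(m); w <- ncol(m)
  ri <- findInterval((seq_len(h) - 0.5) * out / h, 0:out, rightmost.closed = TRUE)
  ci <- findInterval((seq_len(w) - 0.5) * out / w, 0:out, rightmost.closed = TRUE)
  s <- t(rowsum(t(rowsum(m, ri)), ci))
  s / tcrossprod(tabulate(ri, out), tabulate(ci, out))
}

#' Perceptual hash of a frame
#'
#' 64-bit DCT perceptual hash: the frame is converted to luminance, resized
#' to 32x32 by area averaging, transformed with the 2-D DCT-II, and the
#' top-left 8x8 block of low-frequency coefficients is thresholded against
#' the median of those 64 coefficients (DC term included). Coefficients
#' equal to the median map to bit 0. Identical frames yield identical
#' hashes, and the hash is invariant to a uniform brightness offset (away
#' from ties and clipping).
#'
#' @param frame frame (matrix or `h x w x 3` array).
#' @return an object of class `frame_hash`: integer 0/1 vector of 64 bits
#'   (row-major over the 8x8 block) with the 16-character lowercase hex
#'   rendering in attribute `"hex"`.
#' @export
perceptual_hash <- function(frame) {
  g <- as_gray(frame)
  if (nrow(g) < 1L || ncol(g) < 1L) stop("zero-area frame", call. = FALSE)
  small <- .area_resize(g, 32L)
  d <- .dct_rows8 %*% small %*% t(.dct_rows8)  # 8 x 8 low-frequency block
  bits <- as.integer(t(d) > stats::median(d))  # row-major bit order
  frame_hash(bits)
}

#' Construct a frame hash from bits
#'
#' @param bits integer/logical vector of exactly 64 values in \{0, 1\}.
#' @return `frame_hash` object; `attr(, "hex")` holds the hex rendering.
#' @export
frame_hash <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) != 64L || anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("a frame hash is exactly 64 bits", call. = FALSE)
  structure(bits, hex = .bits_to_hex(bits), class = "frame_hash")
}

.bits_to_hex <- function(bits) {
  nib <- matrix(bits, nrow = 4L)  # columns are nibbles, most significant bit first
  vals <- as.integer(crossprod(c(8L, 4L, 2L, 1L), nib))
  paste0(strsplit("0123456789abcdef", "")[[1]][vals + 1L], collapse = "")
}

#' Parse a 16-character hex string into a frame hash
#'
#' @param hex 16-character lowercase hexadecimal string.
#' @return `frame_hash` object; round-trips with `attr(hash, "hex")`.
#' @export
hash_from_hex <- function(hex) {
  if (!is.character(hex) || length(hex) != 1L || !grepl("^[0-9a-f]{16}$", hex))
    stop("expected a 16-character lowercase hex string", call. = FALSE)
  vals <- match(strsplit(hex, "")[[1]], strsplit("0123456789abcdef", "")[[1]]) - 1L
  frame_hash(as.vector(vapply(vals, function(v)
    as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L), integer(4))))
}

#' @export
format.frame_hash <- function(x, ...) attr(x, "hex")

#' @export
print.frame_hash <- function(x, ...) {
  cat("<frame_hash>", attr(x, "hex"), "\n")
  invisible(x)
}

#' Hamming distance between two 64-bit frame hashes
#'
#' @param h1,h2 `frame_hash` objects (or 64-bit 0/1 vectors).
#' @return integer in `[0, 64]`: the number of differing bit positions.
#' @export
hamming_distance <- function(h1, h2) {
  b1 <- as.integer(h1); b2 <- as.integer(h2)
  if (length(b1) != 64L || length(b2) != 64L)
    stop("hashes must be 64 bits", call. = FALSE)
  sum(b1 != b2)
}

#' Speed zone of an inter-frame hash distance
#'
#' Categorizes the Hamming distance `D` between consecutive frame hashes:
#' `normal` for `D <= 20`, `warning` for `21 <= D <= 30` and `danger` for
#' `D > 30` (defaults; the two cut points are configurable and must be
#' strictly increasing). The three zones partition `[0, 64]`.
#'
#' @param distance integer hash distance in `[0, 64]`.
#' @param thresholds length-2 increasing integer vector `c(normal_max,
#'   warning_max)`, default `c(20, 30)`.
#' @return character scalar: `"normal"`, `"warning"` or `"danger"`.
#' @export
speed_zone <- function(distance, thresholds = c(20, 30)) {
  if (!is.numeric(distance) || length(distance) != 1L || is.na(distance) ||
      distance != round(distance) || distance < 0 || distance > 64)
    stop("distance must be an integer in [0, 64]", call. = FALSE)
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2])
    stop("zone thresholds must be strictly increasing", call. = FALSE)
  if (distance <= thresholds[1]) "normal"
  else if (distance <= thresholds[2]) "warning"
  else "danger"
}
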