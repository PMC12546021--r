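# Three-class frame classification contract (ileocecal / instrument / normal)
# with two non-learned implementations, plus the letterbox preprocessing step.

FRAME_LABELS <- c("ileocecal", "instrument", "normal")

#' Construct a frame label
#'
#' @param label one of `"ileocecal"`, `"instrument"`, `"normal"`.
#' @param confidence numeric in `[0, 1]`.
#' @return list with fields `label` and `confidence`.
#' @export
frame_label <- function(label, confidence = 1) {
  if (!is.character(label) || length(label) != 1L || !label %in% FRAME_LABELS)
    stop("label must be one of: ", paste(FRAME_LABELS, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      is.na(confidence) || confidence < 0 || confidence > 1)
    stop("confidence must be in [0, 1]", call. = FALSE)
  list(label = label, confidence = as.numeric(confidence))
}

#' Classify a frame
#'
#' Generic three-class classification contract. Every classifier returns
#' exactly one [frame_label()] per frame. Shipped implementations:
#' [stub_classifier()] (ground-truth sidecar lookup) and
#' [heuristic_classifier()] (marker-signature detector matched to the
#' synthetic generator); [adapter_classifier()] wraps any external callable
#' with the same contract (e.g. an exported network).
#'
#' @param classifier a classifier object.
#' @param frame the frame to classify.
#' @param index 0-based frame index (used by the sidecar stub).
#' @return a [frame_label()].
#' @export
classify <- function(classifier, frame, index) UseMethod("classify")

#' Sidecar-driven stub classifier
#'
#' Looks labels up in a per-frame sidecar table (the ground truth emitted by
#' the synthetic generator, or any table in the same dialect). Used to test
#' the withdrawal engine independently of classifier quality.
#'
#' @param sidecar data frame with columns `frame_index` (0-based,
#'   contiguous), `label`, `confidence`, or a path to such a CSV.
#' @return classifier object.
#' @export
stub_classifier <- function(sidecar) {
  if (is.character(sidecar)) sidecar <- read_sidecar(sidecar)
  stopifnot(is.data.frame(sidecar))
  need <- c("frame_index", "label", "confidence")
  if (!all(need %in% names(sidecar)))
    stop("sidecar must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  sidecar <- sidecar[order(sidecar$frame_index), ]
  if (!identical(as.integer(sidecar$frame_index), seq_len(nrow(sidecar)) - 1L))
    stop("sidecar frame_index must be contiguous from 0", call. = FALSE)
  if (!all(sidecar$label %in% FRAME_LABELS))
    stop("sidecar contains labels outside the closed vocabulary", call. = FALSE)
  structure(list(sidecar = sidecar), class = c("stub_classifier", "classifier"))
}

#' @export
classify.stub_classifier <- function(classifier, frame, index) {
  sc <- classifier$sidecar
  if (index < 0L || index >= nrow(sc))
    stop("no sidecar entry for frame index ", index, call. = FALSE)
  row <- sc[index + 1L, ]
  frame_label(row$label, row$confidence)
}

#' Marker-signature heuristic classifier
#'
#' Detects the synthetic generator's visual signatures: the ileocecal
#' landmark is rendered as a high-contrast annulus (bright ring around a
#' dark ring) centred in the frame; an instrument is a straight
#' high-contrast chord entering from the frame edge. Frames carrying
#' neither signature are labelled normal mucosa. The masks interrogated
#' here are the same documented geometry the generator draws, so the
#' heuristic recovers generator labels; on arbitrary frames it degrades to
#' "normal".
#'
#' @return classifier object.
#' @export
heuristic_classifier <- function() {
  structure(list(), class = c("heuristic_classifier", "classifier"))
}

#' @export
classify.heuristic_classifier <- function(classifier, frame, index) {
  g <- as_gray(frame)
  check_frame(g)
  m <- marker_masks(nrow(g), ncol(g))
  ring_bright <- mean(g[m$ring_outer])
  ring_dark <- mean(g[m$ring_inner])
  if (ring_bright > 200 && ring_dark < 55)
    return(frame_label("ileocecal", min(1, (ring_bright - ring_dark) / 255)))
  chord <- mean(g[m$chord])
  if (chord > 200)
    return(frame_label("instrument", min(1, chord / 255)))
  frame_label("normal", 0.9)
}

#' Adapter for an external classifier callable
#'
#' Extension point for a trained model: wraps any `function(frame, index)`
#' returning a [frame_label()] (or a list with `label` and `confidence`).
#' No model loading or training is implemented here.
#'
#' @param fn the callable.
#' @return classifier object.
#' @export
adapter_classifier <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn), class = c("adapter_classifier", "classifier"))
}

#' @export
classify.adapter_classifier <- function(classifier, frame, index) {
  out <- classifier$fn(frame, index)
  frame_label(out$label, out$confidence)
}

#' Letterbox resize to a square target
#'
#' Scales the content by `min(target/w, target/h)` (aspect ratio preserved
#' exactly), rounds the scaled dimensions half-up to integer pixels,
#' resamples bilinearly, and centres the content on a constant mid-gray
#' (114) canvas with symmetric padding. Already-square frames of the target
#' size pass through unchanged; the operation is idempotent on letterboxed
#' frames.
#'
#' @param frame frame (matrix or `h x w x 3` array).
#' @param target output side length in pixels (default 640).
#' @param pad_value padding intensity (default 114).
#' @return letterboxed frame of size `target x target` (same number of
#'   planes as the input).
#' @export
letterbox_resize <- function(frame, target = 640L, pad_value = 114) {
  check_frame(frame)
  d <- dim(frame)
  h <- d[1]; w <- d[2]
  scale <- min(target / w, target / h)
  nh <- max(1L, as.integer(floor(h * scale + 0.5)))  # round half up
  nw <- max(1L, as.integer(floor(w * scale + 0.5)))
  planes <- if (length(d) == 3L) 3L else 1L
  out <- array(pad_value, dim = c(target, target, planes))
  top <- (target - nh) %/% 2L
  left <- (target - nw) %/% 2L
  for (p in seq_len(planes)) {
    m <- if (planes == 1L) frame else frame[, , p]
    out[top + seq_len(nh), left + seq_len(nw), p] <- .bilinear_resize(m, nh, nw)
  }
  if (planes == 1L) out[, , 1] else out
}

# bilinear resampling with pixel-centre alignment
.bilinear_resize <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  if (nh == h && nw == w) return(m)
  ys <- (seq_len(nh) - 0.5) * h / nh - 0.5
  xs <- (seq_len(nw) - 0.5) * w / nw - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); x0 <- pmin(pmax(floor(xs), 0), w - 1)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * (1 - fy) + m[y1 + 1, x0 + 1, drop = FALSE] * fy
  b <- m[y0 + 1, x1 + 1, drop = FALSE] * (1 - fy) + m[y1 + 1, x1 + 1, drop = FALSE] * fy
  a * rep(1 - fx, each = nh) + b * rep(fx, each = nh)
}

#' Read a label sidecar CSV
#'
#' Dialect: header `frame_index,label,confidence`; labels are the literal
#' strings `ileocecal|instrument|normal`; indices contiguous from 0.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_sidecar <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "label", "confidence")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sidecar ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Write a label sidecar CSV
#'
#' @param sidecar data frame with `frame_index,label,confidence`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(sidecar, path) {
  utils::write.csv(sidecar[, c("frame_index", "label", "confidence")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
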