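# The stateful core: withdrawal-start detection, per-frame time-bucket
# assignment, speed-zone accounting, and the WT / Time 1 / Time 2 / EWT
# summary (EWT = WT - Time 1 - Time 2).

#' Engine configuration
#'
#' @param fps frames per second used to convert frame counts to seconds.
#'   `NA` requests the source's native rate; if none is available the
#'   engine falls back to 25 fps with a warning.
#' @param blur_threshold Laplacian-variance blur threshold (default 50).
#' @param start_run_length number of consecutive ileocecal-classified
#'   processed frames that triggers the withdrawal start (default 5).
#' @param frame_stride process every `frame_stride`-th frame (default 1).
#'   Strides above 1 scale the time accounting by the stride and are an
#'   approximation.
#' @param zone_thresholds strictly increasing `c(normal_max, warning_max)`
#'   Hamming-distance cut points (default `c(20, 30)`).
#' @return list of class `engine_config`.
#' @export
engine_config <- function(fps = NA_real_, blur_threshold = 50,
                          start_run_length = 5L, frame_stride = 1L,
                          zone_thresholds = c(20, 30)) {
  if (!is.na(fps) && (!is.numeric(fps) || fps <= 0))
    stop("fps must be positive", call. = FALSE)
  if (blur_threshold <= 0) stop("blur_threshold must be positive", call. = FALSE)
  if (start_run_length < 1L) stop("start_run_length must be >= 1", call. = FALSE)
  if (frame_stride < 1L) stop("frame_stride must be >= 1", call. = FALSE)
  if (length(zone_thresholds) != 2L || zone_thresholds[1] >= zone_thresholds[2])
    stop("zone_thresholds must be strictly increasing", call. = FALSE)
  structure(list(fps = fps, blur_threshold = blur_threshold,
                 start_run_length = as.integer(start_run_length),
                 frame_stride = as.integer(frame_stride),
                 zone_thresholds = zone_thresholds),
            class = "engine_config")
}

#' Detect the withdrawal start from a label stream
#'
#' Returns the index (0-based, in stream order) of the first frame of the
#' first run of at least `run_length` consecutive `"ileocecal"` labels, or
#' `NA` if no such run exists. An empty stream yields `NA`.
#'
#' @param labels character vector of frame labels in frame order.
#' @param run_length minimum run length (default 5).
#' @return integer index or `NA_integer_`.
#' @export
detect_withdrawal_start <- function(labels, run_length = 5L) {
  if (length(labels) == 0L) return(NA_integer_)
  r <- rle(labels == "ileocecal")
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(ends[hit[1]] - r$lengths[hit[1]])  # 0-based start of the run
}

#' Assign a frame to a time bucket
#'
#' Before the detected withdrawal start every frame is `pre_withdrawal`.
#' After the start, instrument frames count toward Time 1, blurred
#' non-instrument frames toward Time 2, and everything else (including
#' ileocecal-labelled frames) is effective observation. The instrument >
#' blur priority keeps the three buckets disjoint, which the conservation
#' identity EWT = WT - Time 1 - Time 2 requires.
#'
#' @param label frame label string.
#' @param blurred logical blur decision for the frame.
#' @param started logical: has the withdrawal start been reached?
#' @return one of `"pre_withdrawal"`, `"time1"`, `"time2"`, `"effective"`.
#' @export
assign_bucket <- function(label, blurred, started) {
  if (!started) return("pre_withdrawal")
  if (label == "instrument") return("time1")
  if (isTRUE(blurred)) return("time2")
  "effective"
}

#' Run the withdrawal quality-control engine
#'
#' Processes frames in order (honouring `frame_stride`), computing for each
#' processed frame its label, Laplacian variance, blur flag, perceptual
#' hash, Hamming distance to the previous processed frame and speed zone;
#' detects the withdrawal start; assigns every frame to exactly one time
#' bucket; and summarizes WT, Time 1, Time 2 and EWT in frames and seconds
#' together with speed-zone occupancy. WT counts every processed frame from
#' the start frame to the last frame inclusive. Deterministic for fixed
#' inputs.
#'
#' @param frames frame source: list of frames or a PNG directory (see
#'   [frame_source()]).
#' @param classifier a classifier (see [classify()]).
#' @param config an [engine_config()].
#' @param native_fps frame rate of the source container, if known.
#' @return list with `observations` (one row per processed frame:
#'   `frame_index,time_s,label,confidence,lap_var,blurred,phash_hex,
#'   hash_dist,speed_zone,bucket`) and `summary` (see
#'   [summarize_withdrawal()]).
#' @export
run_engine <- function(frames, classifier, config = engine_config(),
                       native_fps = NA_real_) {
  src <- frame_source(frames)
  fps <- config$fps
  if (is.na(fps)) fps <- native_fps
  if (is.na(fps)) {
    warning("frame rate not configured and not recoverable; assuming 25 fps")
    fps <- 25
  }
  stride <- config$frame_stride
  idx <- seq(1L, src$n, by = stride)
  n <- length(idx)
  obs <- data.frame(
    frame_index = integer(n), time_s = numeric(n),
    label = character(n), confidence = numeric(n),
    lap_var = numeric(n), blurred = logical(n),
    phash_hex = character(n), hash_dist = rep(NA_integer_, n),
    speed_zone = rep(NA_character_, n), bucket = character(n),
    stringsAsFactors = FALSE)
  prev_hash <- NULL
  for (k in seq_len(n)) {
    i0 <- idx[k] - 1L                       # 0-based index in the source
    fr <- src$get(idx[k])
    lab <- classify(classifier, fr, i0)
    v <- laplacian_variance(fr)
    h <- perceptual_hash(fr)
    obs$frame_index[k] <- i0
    obs$time_s[k] <- i0 / fps
    obs$label[k] <- lab$label
    obs$confidence[k] <- lab$confidence
    obs$lap_var[k] <- v
    obs$blurred[k] <- is_blurred(v, config$blur_threshold)
    obs$phash_hex[k] <- attr(h, "hex")
    if (!is.null(prev_hash)) {
      d <- hamming_distance(prev_hash, h)
      obs$hash_dist[k] <- d
      obs$speed_zone[k] <- speed_zone(d, config$zone_thresholds)
    }
    prev_hash <- h
  }
  start_pos <- detect_withdrawal_start(obs$label, config$start_run_length)
  started <- if (is.na(start_pos)) rep(FALSE, n) else seq_len(n) - 1L >= start_pos
  obs$bucket <- mapply(assign_bucket, obs$label, obs$blurred, started,
                       USE.NAMES = FALSE)
  summary <- summarize_withdrawal(obs, fps = fps, stride = stride,
                                  config = config)
  list(observations = obs, summary = summary)
}

#' Summarize a per-frame observation table
#'
#' Computes WT / Time 1 / Time 2 / EWT in processed-frame counts and in
#' seconds (`seconds = frames * stride / fps`), plus speed-zone occupancy.
#' The conservation identity `wt = ewt + time1 + time2` holds exactly at
#' frame resolution.
#'
#' @param obs observation table from [run_engine()].
#' @param fps frames per second.
#' @param stride processing stride used to produce `obs`.
#' @param config the engine configuration (echoed into the summary).
#' @return list of class `withdrawal_summary`.
#' @export
summarize_withdrawal <- function(obs, fps, stride = 1L, config = NULL) {
  started <- obs$bucket != "pre_withdrawal"
  start_frame <- if (any(started)) obs$frame_index[which(started)[1]] else NA_integer_
  wt <- sum(started)
  t1 <- sum(obs$bucket == "time1")
  t2 <- sum(obs$bucket == "time2")
  ewt <- wt - t1 - t2
  secs <- function(f) f * stride / fps
  structure(list(
    start_frame = start_frame, fps = fps,
    wt_frames = wt, time1_frames = t1, time2_frames = t2, ewt_frames = ewt,
    wt_s = secs(wt), time1_s = secs(t1), time2_s = secs(t2), ewt_s = secs(ewt),
    frames_total = nrow(obs),
    zone_occupancy = summarize_zones(obs),
    config = if (is.null(config)) NULL else unclass(config)),
    class = "withdrawal_summary")
}

#' Speed-zone occupancy counts
#'
#' Counts processed frames per speed zone. The first processed frame has no
#' predecessor, hence no distance and no zone; the counts therefore sum to
#' `nrow(obs) - 1` (and to 0 for an empty table).
#'
#' @param obs observation table from [run_engine()].
#' @return named integer vector `c(normal, warning, danger)`.
#' @export
summarize_zones <- function(obs) {
  zones <- obs$speed_zone[!is.na(obs$speed_zone)]
  c(normal = sum(zones == "normal"),
    warning = sum(zones == "warning"),
    danger = sum(zones == "danger"))
}

#' @export
print.withdrawal_summary <- function(x, ...) {
  cat("Withdrawal summary @", x$fps, "fps\n")
  cat(sprintf("  start frame : %s\n",
              if (is.na(x$start_frame)) "not detected" else x$start_frame))
  cat(sprintf("  WT    %8.2f s (%d frames)\n", x$wt_s, x$wt_frames))
  cat(sprintf("  Time1 %8.2f s (%d frames, instrument)\n", x$time1_s, x$time1_frames))
  cat(sprintf("  Time2 %8.2f s (%d frames, non-interpretable)\n", x$time2_s, x$time2_frames))
  cat(sprintf("  EWT   %8.2f s (%d frames)\n", x$ewt_s, x$ewt_frames))
  z <- x$zone_occupancy
  cat(sprintf("  speed zones: normal %d / warning %d / danger %d\n",
              z["normal"], z["warning"], z["danger"]))
  invisible(x)
}

#' Write the per-frame observation log as CSV
#'
#' Header: `frame_index,time_s,label,confidence,lap_var,blurred,phash_hex,
#' hash_dist,speed_zone,bucket`.
#'
#' @param obs observation table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_log <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a withdrawal summary as JSON
#'
#' Fields: `start_frame, fps, wt_s, time1_s, time2_s, ewt_s, frames_total,
#' zone_occupancy{normal,warning,danger}` plus the config echo.
#'
#' @param summary a `withdrawal_summary`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  out <- unclass(summary)
  out$zone_occupancy <- as.list(out$zone_occupancy)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
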