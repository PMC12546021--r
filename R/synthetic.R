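# Synthetic withdrawal-video generator with a machine-readable ground-truth
# timeline: mucosa-like texture, an ileocecal marker segment, instrument
# segments, blur episodes with controllable Laplacian variance, and camera
# motion with controllable inter-frame hash distance.
#
# Texture design. Each frame is a window into a large periodic canvas built
# from window-aligned 2-D cosine components (period twice the frame side).
# Translating the window by multiples of the frame side negates a chosen
# subset of the frame's 8x8 low-frequency DCT cells *exactly*, so the
# perceptual-hash Hamming distance between consecutive frames is controlled
# by construction: a small drift keeps D low (normal zone), a one-frame
# diagonal jump flips 22 strong cells (warning), a vertical jump flips 32
# (danger). High-frequency detail that drives the Laplacian variance is a
# frame-anchored grain+vignette layer (a fixed sensor/illumination pattern),
# which keeps sharp frames far above the blur threshold without adding any
# frame-to-frame hash flutter.

GEN_FRAME_SIDE <- 96L    # frame side (px); plaid period is 2x this
GEN_CANVAS <- 960L       # canvas side; multiple of the plaid period (192)

SEGMENT_KINDS <- c("pre_insertion", "ileocecal", "effective", "instrument",
                   "blurred")

# strong plaid cells by (u, v) parity class of the 8x8 DCT block:
#  - all 16 (odd u, odd v) and all 16 (even u incl. 0, odd v) cells, plus
#    6 of the (odd u, even v) cells. A vertical lattice jump negates the
#    32 odd-v cells (danger); a diagonal jump negates the 22 cells with
#    u odd XOR v odd among the strong set (warning).
.plaid_cells <- function() {
  uo <- c(1L, 3L, 5L, 7L); ue <- c(0L, 2L, 4L, 6L)
  rbind(expand.grid(u = uo, v = uo),
        expand.grid(u = ue, v = uo),
        expand.grid(u = c(1L, 3L, 5L), v = c(2L, 4L))[1:6, ])
}

#' Build the procedural texture canvas for a seed
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @return canvas object (plaid matrix, frame-anchored grain and vignette,
#'   geometry constants).
#' @keywords internal
build_canvas <- function(seed) {
  fs <- GEN_FRAME_SIDE; cw <- GEN_CANVAS; period <- 2L * fs
  rng <- .with_seed(seed, {
    cells <- .plaid_cells()
    cells$A <- 4.0 * sample(c(-1, 1), nrow(cells), replace = TRUE)
    grain <- matrix(stats::rnorm(fs * fs, 0, 4), fs, fs)
    list(cells = cells, grain = grain)
  })
  x <- 0:(cw - 1)
  basis <- function(k) cos(pi * k * (2 * x + 1) / period)
  plaid <- matrix(0, cw, cw)
  for (i in seq_len(nrow(rng$cells)))
    plaid <- plaid + rng$cells$A[i] *
      outer(basis(rng$cells$u[i]), basis(rng$cells$v[i]))
  ctr <- (fs + 1) / 2
  r2 <- outer((seq_len(fs) - ctr)^2, (seq_len(fs) - ctr)^2, "+")
  vignette <- -18 * r2 / max(r2)
  list(plaid = plaid, grain = rng$grain, vignette = vignette,
       fs = fs, cw = cw, seed = seed)
}

# run expr with a temporary RNG state; restores the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# render the canvas window at integer position (r, c), with static overlay
.render_window <- function(canvas, r, c) {
  fs <- canvas$fs; cw <- canvas$cw
  ri <- ((r + 0:(fs - 1)) %% cw) + 1L
  ci <- ((c + 0:(fs - 1)) %% cw) + 1L
  128 + canvas$plaid[ri, ci] + canvas$grain + canvas$vignette
}

#' Marker-signature geometry
#'
#' The documented visual signatures shared by the generator and the
#' heuristic classifier: the ileocecal landmark is a bright outer annulus
#' (intensity 255) around a dark inner annulus (0), centred in the frame;
#' an instrument is a straight bright chord (255) entering from the
#' bottom-left frame edge toward the centre.
#'
#' @param h,w frame dimensions in pixels.
#' @return list of logical masks `ring_outer`, `ring_inner`, `chord`.
#' @export
marker_masks <- function(h, w) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+"))
  s <- min(h, w)
  ring_outer <- r >= 0.30 * s & r <= 0.34 * s
  ring_inner <- r >= 0.22 * s & r <= 0.26 * s
  row <- matrix(seq_len(h), h, w)
  col <- matrix(rep(seq_len(w), each = h), h, w)
  chord <- abs((h - row) - col) <= 2 & col <= w / 2
  list(ring_outer = ring_outer, ring_inner = ring_inner, chord = chord)
}

.apply_marker <- function(frame, kind) {
  m <- marker_masks(nrow(frame), ncol(frame))
  if (kind == "ileocecal") {
    frame[m$ring_outer] <- 255
    frame[m$ring_inner] <- 0
  } else if (kind == "instrument") {
    frame[m$chord] <- 255
  }
  frame
}

#' Gaussian smoothing of a frame
#'
#' Separable Gaussian convolution with edge replication; used by the
#' generator to realize blur episodes of controllable Laplacian variance.
#'
#' @param frame grayscale frame matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed frame.
#' @export
gaussian_blur <- function(frame, sigma) {
  stopifnot(is.matrix(frame), sigma > 0)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-half:half, 0, sigma); k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    padded <- rbind(m[rep(1L, half), , drop = FALSE], m,
                    m[rep(n, half), , drop = FALSE])
    out <- stats::filter(padded, k, sides = 2)
    matrix(out[(half + 1):(half + n), ], n, ncol(m))
  }
  t(smooth1(t(smooth1(frame))))
}

#' Scenario specification for the synthetic generator
#'
#' @param segments data frame with columns `kind` (one of `pre_insertion`,
#'   `ileocecal`, `effective`, `instrument`, `blurred`), `duration` (frames,
#'   positive), and optionally `zone` (per-segment target speed zone:
#'   `normal`, `warning` or `danger`; default `normal`) and `sigma`
#'   (Gaussian blur sd for `blurred` segments; default 3).
#' @param fps frames per second of the emitted video (default 10).
#' @param seed integer seed; identical seed + spec give pixel-identical
#'   frames and byte-identical timelines.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(segments, fps = 10, seed = 0L) {
  stopifnot(is.data.frame(segments), nrow(segments) > 0)
  if (!all(c("kind", "duration") %in% names(segments)))
    stop("segments needs columns kind and duration", call. = FALSE)
  if (!all(segments$kind %in% SEGMENT_KINDS))
    stop("unknown segment kind; use one of: ",
         paste(SEGMENT_KINDS, collapse = ", "), call. = FALSE)
  if (any(segments$duration < 1))
    stop("segment durations must be positive", call. = FALSE)
  if (is.null(segments$zone)) segments$zone <- "normal"
  segments$zone[is.na(segments$zone)] <- "normal"
  if (!all(segments$zone %in% c("normal", "warning", "danger")))
    stop("segment zone must be normal, warning or danger", call. = FALSE)
  if (is.null(segments$sigma)) segments$sigma <- NA_real_
  segments$sigma[segments$kind == "blurred" & is.na(segments$sigma)] <- 3
  ileo <- which(segments$kind == "ileocecal")
  if (length(ileo) != 1L)
    stop("exactly one contiguous ileocecal segment is required", call. = FALSE)
  if (ileo > 1L && !all(segments$kind[seq_len(ileo - 1L)] == "pre_insertion"))
    stop("the ileocecal segment must sit at the withdrawal start, ",
         "preceded only by pre_insertion", call. = FALSE)
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  structure(list(segments = segments, fps = fps, seed = as.integer(seed)),
            class = "scenario_spec")
}

.SEGMENT_LABEL <- c(pre_insertion = "normal", ileocecal = "ileocecal",
                    effective = "normal", instrument = "instrument",
                    blurred = "normal")

#' Calibrate translation magnitudes for the requested speed zones
#'
#' For each requested zone, candidate per-frame translations are measured on
#' a trial path over the given canvas, and the first candidate whose
#' realized hash distances fall inside the zone for at least `min_frac` of
#' frames is returned. Deterministic given the canvas (hence the seed).
#'
#' @param canvas canvas from [build_canvas()].
#' @param zones character vector of zones to calibrate (subset of
#'   `normal`, `warning`, `danger`).
#' @param n_trial trial path length in frames (default 40).
#' @param min_frac required in-zone fraction (default 0.9).
#' @return named list of length-2 integer translations `c(dr, dc)`, with the
#'   measured in-zone fraction in attribute `"in_zone"`.
#' @export
calibrate_motion <- function(canvas, zones = c("normal", "warning", "danger"),
                             n_trial = 40L, min_frac = 0.9) {
  fs <- canvas$fs
  candidates <- list(
    normal = list(c(2L, 2L), c(1L, 1L), c(3L, 3L), c(0L, 0L)),
    warning = list(c(fs, fs), c(fs, 0L), c(fs, 3L * fs)),
    danger = list(c(0L, fs), c(2L * fs, fs), c(0L, 3L * fs)))
  bounds <- list(normal = c(0, 20), warning = c(21, 30), danger = c(31, 64))
  out <- list()
  for (z in zones) {
    best <- NULL; best_frac <- -1
    for (cand in candidates[[z]]) {
      pos <- c(0L, 0L)
      prev <- perceptual_hash(.render_window(canvas, pos[1], pos[2]))
      d <- integer(n_trial)
      for (t in seq_len(n_trial)) {
        pos <- pos + cand
        cur <- perceptual_hash(.render_window(canvas, pos[1], pos[2]))
        d[t] <- hamming_distance(prev, cur)
        prev <- cur
      }
      frac <- mean(d >= bounds[[z]][1] & d <= bounds[[z]][2])
      if (frac > best_frac) { best_frac <- frac; best <- cand }
      if (frac >= min_frac) break
    }
    if (best_frac < min_frac)
      stop(sprintf(paste0("zone '%s' unreachable on this texture: best ",
                          "candidate lands %.0f%% of distances in zone ",
                          "(needed %.0f%%)"),
                   z, 100 * best_frac, 100 * min_frac), call. = FALSE)
    out[[z]] <- structure(best, in_zone = best_frac)
  }
  out
}

#' Generate a synthetic withdrawal scenario
#'
#' Renders the frame sequence, the ground-truth timeline and the stub
#' classifier sidecar for a [scenario_spec()]. Ileocecal and instrument
#' frames carry the documented marker signatures (see [marker_masks()]);
#' blurred frames are Gaussian-smoothed so their Laplacian variance falls
#' below 25 (sharp frames are verified to stay at or above 100, twice the
#' default blur threshold, so tests never straddle the decision boundary);
#' camera motion is realized as per-frame canvas translation calibrated per
#' segment to land hash distances in the requested zone. Each segment
#' starts at a fresh lattice-aligned canvas position (a scene
#' repositioning), so within-segment distances follow the motion plan.
#'
#' @param spec a [scenario_spec()].
#' @return list with `frames` (list of grayscale matrices), `timeline`
#'   (per-frame truth: `frame_index, segment, label, blurred, zone,
#'   boundary`), `sidecar` (stub classifier table), `truth` (ground-truth
#'   withdrawal summary with `start_frame`, `wt_frames`, `time1_frames`,
#'   `time2_frames`, `ewt_frames` and their `_s` equivalents), `spec`, and
#'   the calibrated `motion` plan.
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  canvas <- build_canvas(spec$seed)
  segs <- spec$segments
  motion <- calibrate_motion(canvas, unique(segs$zone))
  n <- sum(segs$duration)
  frames <- vector("list", n)
  timeline <- data.frame(
    frame_index = 0:(n - 1), segment = character(n), label = character(n),
    blurred = logical(n), zone = character(n), boundary = logical(n),
    stringsAsFactors = FALSE)
  k <- 0L
  blur_checked <- FALSE; sharp_checked <- FALSE
  for (s in seq_len(nrow(segs))) {
    kind <- segs$kind[s]
    shift <- motion[[segs$zone[s]]]
    # lattice-aligned segment start: scene repositioning between segments
    pos <- c((2L * s * canvas$fs) %% canvas$cw, (s * canvas$fs) %% canvas$cw)
    for (t in seq_len(segs$duration[s])) {
      k <- k + 1L
      fr <- .render_window(canvas, pos[1], pos[2])
      fr <- .apply_marker(fr, kind)
      if (kind == "blurred") {
        fr <- gaussian_blur(fr, segs$sigma[s])
        if (!blur_checked) {
          v <- laplacian_variance(fr)
          if (v >= 25)
            stop(sprintf(paste0("blur plan ineffective: sigma %.2f leaves ",
                                "Laplacian variance %.1f (needs < 25)"),
                         segs$sigma[s], v), call. = FALSE)
          blur_checked <- TRUE
        }
      } else if (!sharp_checked) {
        v <- laplacian_variance(fr)
        if (v < 100)
          stop(sprintf(paste0("texture too smooth: sharp-frame Laplacian ",
                              "variance %.1f (needs >= 100)"), v),
               call. = FALSE)
        sharp_checked <- TRUE
      }
      frames[[k]] <- fr
      timeline$segment[k] <- kind
      timeline$label[k] <- .SEGMENT_LABEL[[kind]]
      timeline$blurred[k] <- kind == "blurred"
      timeline$zone[k] <- segs$zone[s]
      timeline$boundary[k] <- t == 1L
      pos <- pos + shift
    }
  }
  sidecar <- data.frame(frame_index = timeline$frame_index,
                        label = timeline$label, confidence = 1,
                        stringsAsFactors = FALSE)
  list(frames = frames, timeline = timeline, sidecar = sidecar,
       truth = truth_summary(timeline, spec$fps), spec = spec,
       motion = motion)
}

#' Ground-truth withdrawal summary of a timeline
#'
#' Frame-level truth for parameter-recovery tests: the withdrawal starts at
#' the first ileocecal frame; WT counts every frame from there to the end;
#' instrument frames are Time 1; blurred non-instrument frames are Time 2;
#' EWT = WT - Time 1 - Time 2.
#'
#' @param timeline timeline table from [generate_scenario()].
#' @param fps frames per second.
#' @return list with frame counts and seconds.
#' @export
truth_summary <- function(timeline, fps) {
  start <- which(timeline$label == "ileocecal")[1]
  if (is.na(start)) {
    wt <- t1 <- t2 <- 0L
    start_frame <- NA_integer_
  } else {
    start_frame <- timeline$frame_index[start]
    post <- timeline[seq(start, nrow(timeline)), ]
    wt <- nrow(post)
    t1 <- sum(post$label == "instrument")
    t2 <- sum(post$blurred & post$label != "instrument")
  }
  ewt <- wt - t1 - t2
  list(start_frame = start_frame,
       wt_frames = wt, time1_frames = t1, time2_frames = t2,
       ewt_frames = ewt,
       wt_s = wt / fps, time1_s = t1 / fps, time2_s = t2 / fps,
       ewt_s = ewt / fps, fps = fps)
}

#' Random small scenario for property tests
#'
#' Draws a modest scenario (a few hundred frames) whose segment durations,
#' instrument/blur episodes and motion plan vary with the seed.
#'
#' @param seed integer seed.
#' @param fps frames per second (default 10).
#' @return a [scenario_spec()].
#' @export
random_scenario_spec <- function(seed, fps = 10) {
  .with_seed(seed + 1000L, {
    segs <- data.frame(kind = "pre_insertion",
                       duration = sample(5:30, 1), zone = "normal",
                       sigma = NA_real_, stringsAsFactors = FALSE)
    segs <- rbind(segs, data.frame(kind = "ileocecal",
                                   duration = sample(6:20, 1),
                                   zone = "normal", sigma = NA_real_))
    n_ep <- sample(3:6, 1)
    for (i in seq_len(n_ep)) {
      kind <- sample(c("effective", "instrument", "blurred"), 1,
                     prob = c(0.5, 0.25, 0.25))
      zone <- if (kind == "effective")
        sample(c("normal", "warning", "danger"), 1) else "normal"
      segs <- rbind(segs, data.frame(
        kind = kind, duration = sample(10:60, 1), zone = zone,
        sigma = if (kind == "blurred") stats::runif(1, 2.5, 4) else NA_real_))
    }
    segs <- rbind(segs, data.frame(kind = "effective",
                                   duration = sample(20:60, 1),
                                   zone = "normal", sigma = NA_real_))
    scenario_spec(segs, fps = fps, seed = seed)
  })
}

#' The worked-example scenario: a 151 s withdrawal at 10 fps
#'
#' A withdrawal of 2 min 31 s containing 36 s of non-effective time (24 s
#' instrument operation + 12 s blur), so the ground-truth effective
#' withdrawal time is 1 min 55 s.
#'
#' @param seed integer seed (default 0).
#' @return a [scenario_spec()].
#' @export
scenario_case2 <- function(seed = 0L) {
  scenario_spec(data.frame(
    kind = c("pre_insertion", "ileocecal", "effective", "instrument",
             "effective", "blurred", "effective"),
    duration = c(80L, 50L, 400L, 240L, 300L, 120L, 400L),
    zone = c("normal", "normal", "normal", "normal", "danger", "normal",
             "warning"),
    sigma = c(NA, NA, NA, NA, NA, 3, NA),
    stringsAsFactors = FALSE), fps = 10, seed = seed)
}

#' Write a generated scenario to disk
#'
#' Emits a PNG frame directory, the truth timeline (JSON) and the stub
#' sidecar CSV; the three artifacts agree index-by-index.
#'
#' @param scenario result of [generate_scenario()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fdir <- file.path(dir, "frames")
  if (!dir.exists(fdir)) dir.create(fdir)
  n <- length(scenario$frames)
  for (i in seq_len(n))
    write_frame_png(scenario$frames[[i]],
                    file.path(fdir, sprintf("frame_%06d.png", i - 1L)))
  write_sidecar(scenario$sidecar, file.path(dir, "sidecar.csv"))
  jsonlite::write_json(
    list(fps = scenario$spec$fps, seed = scenario$spec$seed,
         truth = scenario$truth, timeline = scenario$timeline),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
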