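# Self-check diagnostics: empirical recovery of the decision boundaries the
# per-frame analyses are configured with.

#' Recover the blur decision boundary by binary search
#'
#' Generates a zero-mean high-frequency pattern whose Laplacian variance
#' scales exactly quadratically with its amplitude (no clipping), then
#' binary-searches the amplitude at which the blur detector's label flips
#' and returns the Laplacian variance at the flip point. For a correctly
#' wired detector this recovers `blur_threshold`.
#'
#' @param blur_threshold detector threshold under test (default 50).
#' @param seed seed for the pattern (the recovered boundary does not depend
#'   on it).
#' @param side pattern side length in pixels (default 64).
#' @param tol binary-search resolution on the variance scale (default 1e-3).
#' @return list with `boundary` (variance at the flip), `amplitude` and the
#'   iteration count.
#' @export
recover_blur_boundary <- function(blur_threshold = 50, seed = 0L, side = 64L,
                                  tol = 1e-3) {
  pat <- .with_seed(seed, matrix(stats::rnorm(side * side), side, side))
  pat <- pat - mean(pat)
  pat <- pat / max(abs(pat))            # unit amplitude, zero mean
  v1 <- laplacian_variance(128 + pat)   # variance at amplitude 1
  frame_at <- function(a) 128 + a * pat # amplitudes kept << 127: no clipping
  lo <- 0
  hi <- sqrt(4 * blur_threshold / v1)   # variance 4x threshold: sharp
  stopifnot(!is_blurred(laplacian_variance(frame_at(hi)), blur_threshold))
  it <- 0L
  while (v1 * (hi^2 - lo^2) > tol) {
    mid <- (lo + hi) / 2
    if (is_blurred(laplacian_variance(frame_at(mid)), blur_threshold))
      lo <- mid else hi <- mid
    it <- it + 1L
  }
  a <- (lo + hi) / 2
  list(boundary = laplacian_variance(frame_at(a)), amplitude = a,
       iterations = it)
}

#' Recover the speed-zone cut points by sweeping all distances
#'
#' Runs every Hamming distance 0..64 through [speed_zone()] and reports the
#' largest distance labelled normal and the largest labelled warning.
#'
#' @param thresholds zone thresholds passed to [speed_zone()].
#' @return list with `normal_max` and `warning_max`.
#' @export
recover_zone_cutpoints <- function(thresholds = c(20, 30)) {
  zones <- vapply(0:64, speed_zone, "", thresholds = thresholds)
  list(normal_max = max(which(zones == "normal")) - 1L,
       warning_max = max(which(zones == "warning")) - 1L)
}
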