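# Live quality-display overlay: WT/EWT timers (mm:ss) in the upper-left
# corner and a color-coded speed scale bar (blue/yellow/red) with a pointer
# at the current inter-frame hash distance.

ZONE_COLORS <- list(normal = c(0, 0, 255), warning = c(255, 255, 0),
                    danger = c(255, 0, 0))

# 3x5 bitmap glyphs (rows top to bottom)
.FONT <- lapply(list(
  "0" = c("111","101","101","101","111"), "1" = c("010","110","010","010","111"),
  "2" = c("111","001","111","100","111"), "3" = c("111","001","111","001","111"),
  "4" = c("101","101","111","001","001"), "5" = c("111","100","111","001","111"),
  "6" = c("111","100","111","101","111"), "7" = c("111","001","001","010","010"),
  "8" = c("111","101","111","101","111"), "9" = c("111","101","111","001","111"),
  ":" = c("000","010","000","010","000"), "E" = c("111","100","111","100","111"),
  "W" = c("101","101","101","111","101"), "T" = c("111","010","010","010","010"),
  " " = c("000","000","000","000","000")),
  function(rows) do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1]]))))

#' Format seconds as mm:ss
#'
#' @param seconds non-negative seconds (fractions truncated).
#' @return character `"mm:ss"` (minutes not zero-capped).
#' @export
format_mmss <- function(seconds) {
  s <- max(0, floor(seconds))
  sprintf("%02d:%02d", s %/% 60, s %% 60)
}

# paint scaled bitmap text into an rgb array; returns the array
.paint_text <- function(rgb, text, top, left, scale = 2L,
                        color = c(255, 255, 255)) {
  col <- left
  for (ch in strsplit(text, "")[[1]]) {
    glyph <- .FONT[[ch]]
    if (is.null(glyph)) glyph <- .FONT[[" "]]
    g <- glyph[rep(seq_len(5), each = scale), rep(seq_len(3), each = scale)]
    rows <- top + seq_len(nrow(g)) - 1L
    cols <- col + seq_len(ncol(g)) - 1L
    ok_r <- rows <= dim(rgb)[1]; ok_c <- cols <= dim(rgb)[2]
    if (any(ok_r) && any(ok_c)) {
      sub <- g[ok_r, ok_c, drop = FALSE] == 1
      for (p in 1:3) {
        plane <- rgb[rows[ok_r], cols[ok_c], p]
        plane[sub] <- color[p]
        rgb[rows[ok_r], cols[ok_c], p] <- plane
      }
    }
    col <- col + 3L * scale + scale  # glyph + 1-glyph-pixel space
  }
  rgb
}

#' Overlay geometry for a frame size
#'
#' The declared rectangles (1-based, inclusive `r0,r1,c0,c1`) the overlay is
#' allowed to touch; [render_overlay()] leaves every pixel outside them
#' unchanged.
#'
#' @param h,w frame dimensions.
#' @param scale text scale factor (2 when the frame fits it, else 1).
#' @return list with `timer` and `bar` rectangles and layout constants.
#' @export
overlay_regions <- function(h, w, scale = NULL) {
  if (is.null(scale)) scale <- if (h >= 64L && w >= 80L) 2L else 1L
  glyph_w <- 4L * scale          # 3 px glyph + 1 px space, scaled
  line_h <- 5L * scale + scale
  timer <- list(r0 = 3L, r1 = 2L + 2L * line_h,
                c0 = 3L, c1 = min(w, 2L + 9L * glyph_w))
  bar_w <- min(w - 6L, 64L)
  bar <- list(r0 = timer$r1 + 2L, r1 = timer$r1 + 2L + 7L,
              c0 = 3L, c1 = 2L + bar_w)
  list(timer = timer, bar = bar, scale = scale, bar_w = bar_w)
}

#' Render the live quality-control overlay onto a frame
#'
#' Draws the running WT and EWT timers as mm:ss in the upper-left corner
#' and a speed scale bar whose three bands use the fixed zone colors (blue
#' = normal, yellow = warning, red = danger) with a white pointer at the
#' current hash distance (monotone in `D`, clamped to `[0, 64]`). Pixels
#' outside the declared [overlay_regions()] are unchanged; rendering is
#' deterministic. Frames too small for the standard footprint are rendered
#' with the text scale reduced, with a warning.
#'
#' @param frame frame (grayscale matrix or `h x w x 3` array).
#' @param wt_s,ewt_s running withdrawal / effective withdrawal time, seconds.
#' @param distance current inter-frame hash distance (or `NA` for none).
#' @param zone_thresholds zone cut points, default `c(20, 30)`.
#' @return `h x w x 3` RGB array (0..255) with attribute
#'   `"overlay_regions"`.
#' @export
render_overlay <- function(frame, wt_s, ewt_s, distance = NA,
                           zone_thresholds = c(20, 30)) {
  check_frame(frame)
  g <- frame
  if (is.matrix(g)) {
    rgb <- array(0, dim = c(nrow(g), ncol(g), 3))
    for (p in 1:3) rgb[, , p] <- g
  } else rgb <- g
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  if (h < 64L || w < 80L)
    warning("frame smaller than the standard overlay footprint; scaling down")
  geo <- overlay_regions(h, w)
  sc <- geo$scale
  line_h <- 5L * sc + sc
  rgb <- .paint_text(rgb, paste0(" WT ", format_mmss(wt_s)), 3L, 3L, sc)
  rgb <- .paint_text(rgb, paste0("EWT ", format_mmss(ewt_s)), 3L + line_h, 3L, sc)
  # speed scale bar: column j maps to distance (j-1)/(bar_w-1) * 64
  bar <- geo$bar
  cols <- bar$c0:bar$c1
  dvals <- (seq_along(cols) - 1) / (length(cols) - 1) * 64
  for (j in seq_along(cols)) {
    zone <- if (dvals[j] <= zone_thresholds[1]) "normal"
    else if (dvals[j] <= zone_thresholds[2]) "warning" else "danger"
    colr <- ZONE_COLORS[[zone]]
    for (p in 1:3) rgb[(bar$r0 + 2L):bar$r1, cols[j], p] <- colr[p]
  }
  if (!is.na(distance)) {
    d <- min(max(distance, 0), 64)
    jptr <- cols[1] + as.integer(round(d / 64 * (length(cols) - 1)))
    for (p in 1:3) rgb[bar$r0:(bar$r0 + 1L), jptr, p] <- 255
    for (p in 1:3) rgb[(bar$r0 + 2L):bar$r1, jptr, p] <- 255
  }
  attr(rgb, "overlay_regions") <- geo
  rgb
}
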