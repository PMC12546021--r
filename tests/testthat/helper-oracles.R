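# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the implementation they check.

# 3x3 4-neighbour Laplacian with edge replication, explicit double loop,
# population variance of the response
naive_laplacian_variance <- function(m) {
  h <- nrow(m); w <- ncol(m)
  at <- function(i, j) m[min(max(i, 1), h), min(max(j, 1), w)]
  resp <- numeric(h * w)
  k <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    k <- k + 1
    resp[k] <- at(i - 1, j) + at(i + 1, j) + at(i, j - 1) + at(i, j + 1) -
      4 * at(i, j)
  }
  mean((resp - mean(resp))^2)
}

# perceptual hash recomputed from first principles: explicit area-average
# resize, direct double-sum DCT-II, median threshold over the 8x8 block
naive_phash_bits <- function(m) {
  h <- nrow(m); w <- ncol(m)
  small <- matrix(0, 32, 32)
  for (bi in 1:32) for (bj in 1:32) {
    rows <- which(findInterval((seq_len(h) - 0.5) * 32 / h, 0:32,
                               rightmost.closed = TRUE) == bi)
    cols <- which(findInterval((seq_len(w) - 0.5) * 32 / w, 0:32,
                               rightmost.closed = TRUE) == bj)
    small[bi, bj] <- mean(m[rows, cols])
  }
  d <- matrix(0, 8, 8)
  for (u in 0:7) for (v in 0:7) {
    acc <- 0
    for (x in 0:31) for (y in 0:31)
      acc <- acc + small[x + 1, y + 1] *
        cos(pi * (2 * x + 1) * u / 64) * cos(pi * (2 * y + 1) * v / 64)
    d[u + 1, v + 1] <- 4 * acc
  }
  med <- median(d)
  as.integer(t(d) > med)
}

# bit-by-bit Hamming distance
bit_loop_hamming <- function(b1, b2) {
  n <- 0L
  for (i in seq_along(b1)) if (b1[i] != b2[i]) n <- n + 1L
  n
}

# AUC as the Mann-Whitney pairwise-comparison probability
mw_auc <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

# AP by an exhaustive sweep over distinct thresholds, trapezoid over recall
sweep_ap <- function(scores, truth) {
  truth <- as.logical(truth)
  th <- sort(unique(scores), decreasing = TRUE)
  rec <- 0; prevr <- 0; prevp <- NA; ap <- 0
  pts <- data.frame(r = numeric(0), p = numeric(0))
  for (t in th) {
    sel <- scores >= t
    p <- sum(truth & sel) / sum(sel)
    r <- sum(truth & sel) / sum(truth)
    pts <- rbind(pts, data.frame(r = r, p = p))
  }
  pts <- rbind(data.frame(r = 0, p = pts$p[1]), pts)
  sum(diff(pts$r) * (pts$p[-1] + pts$p[-nrow(pts)]) / 2)
}

# first index (0-based) of a run of >= k consecutive "ileocecal" labels,
# by exhaustive scan
scan_start <- function(labels, k) {
  n <- length(labels)
  if (n >= k) for (i in seq_len(n - k + 1))
    if (all(labels[i:(i + k - 1)] == "ileocecal")) return(i - 1L)
  NA_integer_
}

# small random frame on the 0..255 scale
random_frame <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w, 0, 255), h, w)
}

# a small cached scenario shared by several test files
cached_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_scenario(random_scenario_spec(1))
    cache
  }
})
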