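# Independent oracles used across tests.

# Monte-Carlo point-in-region estimate of the circle-strip intersection
# {(u, v): u^2 + v^2 <= r^2, |v| <= width/2}, with its standard error.
mc_strip_area <- function(width, area_AG, n = 1e6, seed = 1) {
  r <- sqrt(area_AG / pi)
  y <- min(width / 2, r)
  hits <- 0
  left <- n
  withr::with_seed(seed, {
    while (left > 0) {
      m <- min(left, 2.5e6)
      u <- stats::runif(m, -r, r)
      v <- stats::runif(m, -r, r)
      hits <- hits + sum(u * u + v * v <= r * r & abs(v) <= y)
      left <- left - m
    }
  })
  p <- hits / n
  list(est = p * (2 * r)^2, se = sqrt(p * (1 - p) / n) * (2 * r)^2)
}

# Single closed-form expression for the width-based area, written directly
# from its algebraic form (independent of the package's stepwise build).
closed_form_wal <- function(W, AG) {
  r <- sqrt(AG / pi)
  W <- pmin(W, 2 * r)
  AG - 2 * AG * acos(W / (2 * sqrt(AG / pi))) / pi +
    W * sqrt(AG / pi - W^2 / 4)
}

# Rotate a matrix image by 90 degrees clockwise.
rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# 2x block-average downsampling.
downsample2 <- function(m) {
  nr <- 2 * (nrow(m) %/% 2)
  nc <- 2 * (ncol(m) %/% 2)
  m <- m[seq_len(nr), seq_len(nc)]
  0.25 * (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
          m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)])
}

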