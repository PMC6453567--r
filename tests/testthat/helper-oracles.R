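# Independent oracles used across the suite; each is deliberately naive.

# dense log-grid argmin of the film stress (oracle for the 1-D minimiser)
grid_ncr <- function(stack, n_grid = 1e4, lo = 1e-3, hi = 1e3) {
  ns <- exp(seq(log(lo / stack$film$h), log(hi / stack$film$h),
                length.out = n_grid))
  S <- film_stress(ns, stack)
  ns[which.min(S)]
}

# analytic curvature of the polar curve r(theta)
polar_curvature <- function(r, rp, rpp) {
  (r^2 + 2 * rp^2 - r * rpp) / (r^2 + rp^2)^1.5
}

# O(M^2) brute-force circular topographic prominence
brute_prominences <- function(y) {
  M <- length(y)
  yy <- c(y, y, y)  # unwrap three periods, analyse the middle one
  res <- NULL
  for (i in seq_len(M)) {
    p <- i + M
    if (!(yy[p] > yy[p - 1] && yy[p] >= yy[p + 1])) next
    h <- yy[p]
    lows <- c()
    for (dir in c(-1, 1)) {
      lowest <- h
      for (s in 1:(M - 1)) {
        v <- yy[p + dir * s]
        if (v > h) break
        lowest <- min(lowest, v)
      }
      lows <- c(lows, lowest)
    }
    res <- rbind(res, c(index = i, prominence = h - max(lows)))
  }
  as.data.frame(res)
}

# disk mask fixture
disk_mask <- function(size, cx, cy, radius) {
  X <- matrix(0:(size - 1), size, size, byrow = TRUE)
  Y <- matrix(0:(size - 1), size, size)
  (X - cx)^2 + (Y - cy)^2 <= radius^2
}
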