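# Independent brute-force oracles used to cross-check the fast paths.

# k nearest neighbours by exhaustive pairwise search with (distance, index)
# ordering, mirroring the documented tie-break.
brute_knn <- function(pos, k) {
  n <- nrow(pos)
  keff <- min(k, n - 1L)
  out <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(pos) - pos[i, ])^2))
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    out[i, seq_len(keff)] <- ord[seq_len(keff)]
  }
  out
}

# mean nearest-neighbour distance over all pairs
brute_mean_nnd <- function(pos) {
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

# uniformly sampled trajectory data.frame from a position function of time
traj_from_fn <- function(fn, t_end = 10, dt = 0.01) {
  tt <- seq(0, t_end, by = dt)
  p <- t(vapply(tt, fn, numeric(3)))
  trajectory(tt, p[, 1], p[, 2], p[, 3])
}

# random smooth-ish trajectory for property tests
random_traj <- function(n = 50, dt = 0.1) {
  p <- apply(matrix(rnorm(3 * n), n, 3), 2, cumsum)
  trajectory(seq(0, by = dt, length.out = n), p[, 1], p[, 2], p[, 3])
}

# small flock state at given positions (unit +x velocities)
state_from_positions <- function(pos, speed = 10) {
  cfg <- flock_config(nrow(pos), seed = 1)
  st <- init_flock(cfg)
  st$pos <- pos
  st$vel <- matrix(rep(c(speed, 0, 0), each = nrow(pos)), nrow(pos), 3)
  st
}
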