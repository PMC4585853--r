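# Independent brute-force oracles and small shared fixtures.

# direct double-loop spatial correlation at a single lag
direct_correlation <- function(a, b, xi, psi) {
  M <- nrow(a); N <- ncol(a)
  da <- a - mean(a); db <- b - mean(b)
  tot <- 0; n <- 0L
  for (y in seq_len(M)) for (x in seq_len(N)) {
    y2 <- y + psi; x2 <- x + xi
    if (y2 >= 1 && y2 <= M && x2 >= 1 && x2 <= N) {
      tot <- tot + da[y, x] * db[y2, x2]
      n <- n + 1L
    }
  }
  tot / n / (mean(a) * mean(b))
}

# direct per-frame moving-average detrend (subtract mode); the restored
# scalar is the mean of the trend so the stack mean is preserved exactly
direct_detrend <- function(arr, window) {
  nf <- dim(arr)[1]
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  avgs <- arr
  for (f in seq_len(nf)) {
    lo <- max(1L, f - half_lo); hi <- min(nf, f + half_hi)
    avgs[f, , ] <- apply(arr[lo:hi, , , drop = FALSE], c(2, 3), mean)
  }
  arr - avgs + mean(avgs)
}

# small fast simulation: homogeneous field of diffusing particles
quick_sim <- function(fraction_double, n_frames = 20L, size = 96L,
                      n_particles = 60L, D = 100, seed = 1L,
                      brightness = 5, background = 0.5) {
  cfg <- solution_protocol(fraction_double = fraction_double,
                           n_particles = n_particles, D = D,
                           n_frames = n_frames, n_rows = size,
                           n_cols = size,
                           total_time = n_frames * size * size * 12.8e-6,
                           brightness = brightness, background = background,
                           seed = seed)
  list(config = cfg, sim = simulate_stack(cfg))
}
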