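test_that("detrending removes static structure and preserves the mean", {
  # identical frames: all spatial structure is "immobile" and is removed
  frame <- matrix(runif(64, 1, 9), 8, 8)
  arr <- aperm(array(frame, c(8, 8, 6)), c(3, 1, 2))
  st <- image_stack(arr, "green")
  out <- detrend(st, 3)
  expect_equal(as.vector(out$data), rep(mean(arr), length(arr)),
               tolerance = 1e-12)
  # mean preservation on a random stack
  set.seed(10)
  st2 <- image_stack(array(rpois(5 * 16 * 16, 8), c(5, 16, 16)), "red")
  out2 <- detrend(st2, 3)
  expect_equal(mean(out2$data), mean(st2$data), tolerance = 1e-9)
  # window validation
  expect_error(detrend(st2, 1), "window")
  expect_error(detrend(st2, 6), "window")
})

test_that("detrending matches the direct loop oracle, including boundaries", {
  set.seed(11)
  arr <- array(rpois(7 * 6 * 9, 12), c(7, 6, 9))
  st <- image_stack(arr, "green")
  for (w in c(2L, 3L, 5L)) {
    expect_equal(detrend(st, w)$data, direct_detrend(arr, w),
                 tolerance = 1e-12, label = paste("window", w))
  }
  # replace mode literally substitutes the moving average
  rep3 <- detrend(st, 3, mode = "replace")$data
  expect_equal(rep3[4, , ], apply(arr[3:5, , ], c(2, 3), mean),
               tolerance = 1e-12)
})

test_that("spatial correlation reproduces hand-computed and brute-force values", {
  # single hot pixel: G(0,0) = 15 on a 4x4 image
  img <- matrix(0, 4, 4); img[2, 3] <- 16
  s <- spatial_correlation(img, img, "ACF_green")
  expect_equal(s$G[s$psi_lags == 0, s$xi_lags == 0], 15)
  # FFT equals the direct double-loop sum at every lag
  set.seed(12)
  a <- matrix(rexp(256) + 0.2, 16, 16)
  b <- matrix(rexp(256) + 0.2, 16, 16)
  s2 <- spatial_correlation(a, b, "CCF")
  for (xi in s2$xi_lags) for (psi in s2$psi_lags) {
    expect_equal(s2$G[s2$psi_lags == psi, s2$xi_lags == xi],
                 direct_correlation(a, b, xi, psi), tolerance = 1e-10,
                 label = sprintf("lag (%d, %d)", xi, psi))
  }
})

test_that("degenerate images are rejected or zeroed per flag", {
  z <- matrix(0, 8, 8)
  expect_error(spatial_correlation(z, z, "ACF_green"), "degenerate")
  const <- matrix(3, 8, 8)
  expect_error(spatial_correlation(const, const, "ACF_green"), "degenerate")
  s <- spatial_correlation(const, const, "ACF_green", on_constant = "zero")
  expect_true(all(s$G == 0))
})

test_that("ACF surfaces are exactly even-symmetric", {
  set.seed(13)
  for (rep in 1:3) {
    img <- matrix(rpois(32 * 24, 6) + 0.0, 32, 24)
    s <- spatial_correlation(img, img, "ACF_green")
    flipped <- s$G[rev(seq_along(s$psi_lags)), rev(seq_along(s$xi_lags))]
    expect_equal(s$G, flipped, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("surface averaging is element-wise with bookkeeping", {
  img <- matrix(rpois(64, 5) + 0.0, 8, 8)
  s <- spatial_correlation(img, img, "ACF_green")
  avg <- average_surfaces(list(s, s, s))
  expect_equal(avg$G, s$G)
  expect_equal(avg$n_frames_averaged, 3L)
  # linearity: average of {G, -G} is zero
  neg <- s; neg$G <- -s$G
  expect_true(all(average_surfaces(list(s, neg))$G == 0))
  # mismatched kinds or axes are rejected
  s_red <- s; s_red$kind <- "ACF_red"
  expect_error(average_surfaces(list(s, s_red)), "mixed kinds")
  s_trim <- spatial_correlation(img, img, "ACF_green", max_lag_xi = 1)
  expect_error(average_surfaces(list(s, s_trim)), "lag axes")
})

test_that("frame averaging reduces estimator variance ~ 1/n_frames", {
  # per-frame G(1,0) variance vs 10-frame average variance across seeds
  per_frame <- c(); averaged <- c()
  for (seed in 1:8) {
    qs <- quick_sim(1, n_frames = 10, size = 48, n_particles = 20,
                    seed = seed)
    st <- qs$sim$green
    g10 <- vapply(1:10, function(f) {
      s <- spatial_correlation(get_frame(st, f), get_frame(st, f), "ACF_green")
      s$G[s$psi_lags == 0, s$xi_lags == 1]
    }, 0)
    per_frame <- c(per_frame, g10)
    averaged <- c(averaged, mean(g10))
  }
  ratio <- var(averaged) / var(per_frame)
  expect_lt(ratio, 0.35)  # ~1/10 expected; generous for 8 replicate seeds
})

test_that("independent channels decorrelate and detrending removes fixed patterns", {
  qs <- quick_sim(0, n_frames = 15, size = 64, n_particles = 40, seed = 21)
  sim <- qs$sim
  s_c <- stack_correlation(sim$green, sim$red, kind = "CCF")
  near0 <- abs(s_c$G[abs(s_c$psi_lags) <= 1, abs(s_c$xi_lags) <= 1])
  s_g <- stack_correlation(sim$green, kind = "ACF_green")
  amp <- s_g$G[s_g$psi_lags == 0, s_g$xi_lags == 1]
  expect_lt(max(near0), 0.1 * amp)

  # static bright structure: ACF after detrend matches particles-only ACF
  qs2 <- quick_sim(1, n_frames = 15, size = 64, n_particles = 40, seed = 22)
  clean <- qs2$sim$green
  pattern <- outer(seq(0, 4, length.out = 64), seq(0, 4, length.out = 64))
  dirty_arr <- sweep(clean$data, c(2, 3), pattern, `+`)
  dirty <- image_stack(dirty_arr, "green", clean$frame_interval)
  # compare fluctuation covariances (G * mean^2): the added structure
  # raises the mean, so normalized G is diluted even after detrending
  cov_profile <- function(st, dtw) {
    d <- if (is.null(dtw)) st else detrend(st, dtw)
    xi_profile(stack_correlation(d), 1, 10)$G * mean(d$data)^2
  }
  cov_clean <- cov_profile(clean, 3)
  cov_dirty <- cov_profile(dirty, 3)
  cov_raw <- cov_profile(dirty, NULL)
  # without detrending the static gradient inflates the correlation
  expect_gt(mean(cov_raw), 2 * mean(cov_clean))
  expect_equal(cov_dirty, cov_clean, tolerance = 0.25)
})
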