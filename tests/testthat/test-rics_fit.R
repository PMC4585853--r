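geom_ref <- acq_geometry(0.022, 12.8e-6, 3.5e-3, 0.2, 1, gamma = 0.35,
                         n_rows = 256, n_cols = 256)

test_that("scanning term matches closed forms and the frozen oracle", {
  expect_equal(scan_term(0, 0, geom_ref, 123), 1)
  # D = 0, pixel size = w0, one-pixel lag: exp(-1)
  g1 <- acq_geometry(0.2, 1e-5, 32e-5, 0.2, 1, n_rows = 32, n_cols = 32)
  expect_equal(scan_term(1, 0, g1, 0), exp(-1))
  # independently scripted evaluation of the formula (frozen value)
  expect_equal(scan_term(10, 0, geom_ref, 10), 0.3420853418550497,
               tolerance = 1e-12)
  # values in (0, 1] over a lag sweep
  v <- scan_term(-20:20, rep(c(-2, 0, 2), length.out = 41), geom_ref, 5)
  expect_true(all(v > 0 & v <= 1))
})

test_that("diffusion term matches closed forms and the frozen oracle", {
  expect_equal(diffusion_term(0, 0, geom_ref, N = 10, D = 7), 0.035)
  # no decay without diffusion
  expect_equal(diffusion_term(c(0, 5, 50), 0, geom_ref, N = 4, D = 0),
               rep(0.35 / 4, 3))
  # frozen independent evaluations
  expect_equal(diffusion_term(10, 0, geom_ref, N = 5, D = 10),
               0.06189847979173778, tolerance = 1e-12)
  g2 <- geom_ref
  expect_equal(diffusion_term(3, 1, g2, N = 12, D = 25), 0.00254591146099162,
               tolerance = 1e-12)
  expect_error(diffusion_term(0, 0, geom_ref, N = 0, D = 1), "N must be > 0")
  # monotone non-increasing in the lag-time combination
  tau_ord <- order(geom_ref$pixel_dwell * 0:30)
  v <- diffusion_term(0:30, 0, geom_ref, N = 3, D = 50)[tau_ord]
  expect_true(all(diff(v) <= 0))
})

test_that("fitting a noiseless model profile recovers N and D exactly", {
  for (case in list(c(N = 5, D = 5), c(N = 0.3, D = 120), c(N = 40, D = 0.5))) {
    prof <- data.frame(xi = 1:64,
                       G = rics_model(1:64, 0, geom_ref, case["N"], case["D"]))
    fit <- fit_xi_profile(prof, geom_ref)
    expect_equal(fit$N, unname(case["N"]), tolerance = 1e-6)
    expect_equal(fit$D, unname(case["D"]), tolerance = 1e-6)
    expect_lt(fit$residual, 1e-16)
  }
  # D = 0 boundary is reachable
  prof0 <- data.frame(xi = 1:32, G = rics_model(1:32, 0, geom_ref, 2, 0))
  fit0 <- fit_xi_profile(prof0, geom_ref)
  expect_equal(fit0$D, 0)
  expect_equal(fit0$N, 2, tolerance = 1e-9)
})

test_that("degenerate profiles are flagged, not silently fitted", {
  zero <- data.frame(xi = 1:16, G = rep(0, 16))
  expect_equal(fit_xi_profile(zero, geom_ref)$status, "failed")
  short <- data.frame(xi = 1:5, G = rnorm(5))
  expect_equal(fit_xi_profile(short, geom_ref)$status, "failed")
  neg <- data.frame(xi = 1:16, G = -rics_model(1:16, 0, geom_ref, 5, 5))
  expect_equal(fit_xi_profile(neg, geom_ref, amplitude = "positive")$status,
               "failed")
  # CCF-style free amplitude reports the floor instead
  fit_free <- fit_xi_profile(neg, geom_ref, amplitude = "free")
  expect_equal(fit_free$status, "amplitude_floor")
  expect_lt(fit_free$amplitude, 0)
})

test_that("fitted profiles are non-increasing for xi >= 0", {
  set.seed(30)
  for (rep in 1:5) {
    prof <- data.frame(
      xi = 1:32,
      G = rics_model(1:32, 0, geom_ref, runif(1, 0.2, 20),
                     10^runif(1, -1, 2.5)) * (1 + rnorm(32, 0, 0.05)))
    fit <- fit_xi_profile(prof, geom_ref)
    curve <- fit$amplitude * scan_term(0:64, 0, geom_ref, fit$D) *
      diffusion_term(0:64, 0, geom_ref, 1, fit$D) / geom_ref$gamma
    expect_true(all(diff(curve) <= 1e-12))
  }
})

test_that("ground-truth recovery from a simulated stack", {
  # solution regime: fast diffusion, where D is identifiable from the decay
  qs <- quick_sim(1, n_frames = 25, size = 128, n_particles = 100, D = 100,
                  seed = 31, background = 0)
  res <- ccrics_analysis(qs$sim$green, qs$sim$red, qs$config$geometry,
                         detrend_window = NULL)
  expect_equal(res$N_g, qs$sim$truth$N_green, tolerance = 0.2)
  expect_equal(res$D_g, 100, tolerance = 0.3)
  expect_equal(res$D_r, 100, tolerance = 0.3)
})

test_that("RCA algebra follows the cross-amplitude relation", {
  mk <- function(N, D = 10, kind = "profile") {
    structure(list(N = N, D = D, amplitude = geom_ref$gamma / N,
                   residual = 0, n_points = 16, status = "ok",
                   kind = kind, geometry = geom_ref), class = "rics_fit")
  }
  r1 <- compute_rca(mk(10), mk(10), mk(10))
  expect_equal(r1$N_gr, 10)
  expect_equal(r1$RCA, 1)
  # N_g = 20, N_r = 10, N_c = 40 -> N_gr = 5, RCA = 0.25
  r2 <- compute_rca(mk(20), mk(10), mk(40))
  expect_equal(r2$N_gr, 5)
  expect_equal(r2$RCA, 0.25)
  # non-positive cross amplitude: independent channels, RCA = 0
  floor_fit <- mk(10); floor_fit$amplitude <- -1e-4; floor_fit$N <- Inf
  floor_fit$status <- "amplitude_floor"
  r3 <- compute_rca(mk(10), mk(10), floor_fit)
  expect_equal(r3$RCA, 0)
  expect_equal(r3$N_gr, 0)
  # failed channel propagates
  failed <- mk(10); failed$status <- "failed"
  expect_equal(compute_rca(failed, mk(10), mk(10))$status, "failed")
})

test_that("RCA recovers the configured double-labeled fraction", {
  # reduced scale: 96 px, 20 frames; acceptance runs the larger protocol
  for (f in c(0, 0.5, 1)) {
    qs <- quick_sim(f, n_frames = 20, size = 96, n_particles = 60,
                    seed = 32 + round(10 * f))
    res <- ccrics_analysis(qs$sim$green, qs$sim$red, qs$config$geometry)
    expect_lt(abs(res$RCA - f), 0.1,
              label = sprintf("|RCA - %.2f| at that fraction", f))
    expect_gte(res$RCA, 0)
    expect_lte(res$RCA, 1.15)
  }
})
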