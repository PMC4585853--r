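test_that("half-overlap tiling reproduces the printed grid counts", {
  g1024 <- tile_rois(c(1024, 1024), 64)
  expect_equal(c(g1024$n_grid_rows, g1024$n_grid_cols), c(32L, 32L))
  expect_equal(g1024$anchor_stride, 32L)
  # 256 px -> 8 anchors; the last window is truncated to stride width
  g256 <- tile_rois(c(256, 256), 64)
  expect_equal(c(g256$n_grid_rows, g256$n_grid_cols), c(8L, 8L))
  last <- g256$windows[[length(g256$windows)]]
  expect_equal(last$row_start, 224L)
  expect_equal(last$height, 32L)
  expect_equal(last$width, 32L)
  expect_error(tile_rois(c(32, 32), 64), "exceeds")
})

test_that("every pixel belongs to between 1 and 4 ROIs", {
  for (shape in list(c(1024L, 1024L), c(256L, 192L))) {
    g <- tile_rois(shape, 64)
    cover <- matrix(0L, shape[1], shape[2])
    for (w in g$windows) {
      rows <- (w$row_start + 1):(w$row_start + w$height)
      cols <- (w$col_start + 1):(w$col_start + w$width)
      cover[rows, cols] <- cover[rows, cols] + 1L
    }
    expect_gte(min(cover), 1L)
    expect_lte(max(cover), 4L)
  }
})

test_that("homogeneous double-labeled field maps to uniformly high RCA", {
  qs <- quick_sim(1, n_frames = 16, size = 96, n_particles = 80, seed = 50)
  map <- map_rca(qs$sim$green, qs$sim$red, qs$config$geometry, roi_size = 32,
                 frames_per_block = 10, block_mode = "disjoint")
  expect_s3_class(map, "rca_map")
  vals <- map$rca[1, , ]
  defined <- which(!is.na(vals), arr.ind = TRUE)
  expect_gt(nrow(defined), 8)
  expect_gte(mean(vals[defined]), 0.8)
  # no spatial gradient: regression of RCA on grid position ~ flat
  df <- data.frame(rca = vals[defined], row = defined[, 1], col = defined[, 2])
  fit <- lm(rca ~ row + col, data = df)
  pvals <- summary(fit)$coefficients[-1, 4]
  expect_gt(min(pvals), 0.01)
  # block times are strictly increasing mid-times
  expect_true(all(diff(map$block_times) > 0))
})

test_that("two-region stack discriminates intact from degraded regions", {
  # left half: double-labeled; right half: independent channels
  g <- acq_geometry(0.022, 12.8e-6, 96 * 12.8e-6, 0.2, 1,
                    n_rows = 96, n_cols = 48)
  mk_half <- function(frac, seed) {
    n_dbl <- round(frac * 40); n_single <- 40 - n_dbl
    sp <- list()
    if (n_dbl > 0) sp <- c(sp, list(species_spec("double", n_dbl, 100)))
    if (n_single > 0)
      sp <- c(sp, list(species_spec("green_only", n_single, 100),
                       species_spec("red_only", n_single, 100)))
    simulate_stack(sim_config(g, sp, n_frames = 12, seed = seed))
  }
  left <- mk_half(1, 51); right <- mk_half(0, 52)
  glue <- function(a, b) {
    arr <- array(0, dim = c(12, 96, 96))
    arr[, , 1:48] <- a$data; arr[, , 49:96] <- b$data
    image_stack(arr, a$channel, a$frame_interval)
  }
  geom_full <- acq_geometry(0.022, 12.8e-6, 96 * 12.8e-6, 0.2, 1,
                            n_rows = 96, n_cols = 96)
  map <- map_rca(glue(left$green, right$green), glue(left$red, right$red),
                 geom_full, roi_size = 32, frames_per_block = 10,
                 block_mode = "disjoint")
  rca1 <- map$rca[1, , ]
  # grid columns whose windows lie fully inside one half (the straddling
  # middle anchor mixes both populations)
  starts <- vapply(map$grid$windows[seq_len(map$grid$n_grid_cols)],
                   function(w) w$col_start + c(0L, w$width), c(0L, 0L))
  left_cols <- which(starts[2, ] <= 48L)
  right_cols <- which(starts[1, ] >= 48L)
  left_mean <- mean(rca1[, left_cols], na.rm = TRUE)
  right_mean <- mean(rca1[, right_cols], na.rm = TRUE)
  expect_gte(left_mean - right_mean, 0.5)
})

test_that("map_rca validates the block length", {
  qs <- quick_sim(1, n_frames = 5, size = 64, n_particles = 10, seed = 53)
  expect_error(map_rca(qs$sim$green, qs$sim$red, qs$config$geometry,
                       roi_size = 32, frames_per_block = 10),
               "frames_per_block")
})

test_that("rendering respects the intensity-modulation contract", {
  grid <- tile_rois(c(64, 64), 32)
  shape <- c(1, grid$n_grid_rows, grid$n_grid_cols)
  mk_map <- function(rca_val, int_val) {
    structure(list(
      rca = array(rca_val, shape), D_g = array(NA, shape),
      D_r = array(NA, shape), status = array("ok", shape),
      intensity_green = array(int_val, shape),
      intensity_red = array(int_val, shape),
      block_times = 0, grid = grid, frames_per_block = 1L),
      class = "rca_map")
  }
  # constant RCA = 1, uniform intensity: uniform top-of-scale (red) frame
  img <- render_map(mk_map(1, 10))
  expect_equal(dim(img), c(64L, 64L, 3L))
  expect_true(all(abs(img[, , 1] - 1) < 1e-12))  # red channel saturated
  expect_true(all(img[, , 3] == 0))              # no blue
  # zero intensity: black regardless of RCA
  img0 <- render_map(mk_map(1, 0))
  expect_true(all(img0 == 0))
  # undefined ROI: dark, never interpolated over
  m <- mk_map(1, 10)
  m$rca[1, 2, 2] <- NA; m$status[1, 2, 2] <- "fit_failed"
  imgNA <- render_map(m)
  w <- grid$windows[[(2 - 1) * grid$n_grid_cols + 2]]
  cr <- w$row_start + w$height %/% 2; cc <- w$col_start + w$width %/% 2
  expect_equal(sum(imgNA[cr, cc, ]), 0)
  # smooth input renders continuously across ROI borders (no blocking)
  vals <- outer(seq(0, 1, length.out = shape[2]),
                seq(0, 1, length.out = shape[3]), function(a, b) (a + b) / 2)
  ms <- mk_map(0, 10); ms$rca[1, , ] <- vals
  imgS <- render_map(ms)
  jumps <- abs(diff(imgS[, 32, 2]))  # green channel down a column
  expect_lt(max(jumps), 0.08)
})

test_that("ROI time courses aggregate nine grid cells", {
  shape <- c(4, 5, 5)
  map <- structure(list(
    rca = array(0.4, shape), D_g = array(NA, shape), D_r = array(NA, shape),
    status = array("ok", shape),
    intensity_green = array(1, shape), intensity_red = array(1, shape),
    block_times = (0:3) * 2, grid = tile_rois(c(160, 160), 64),
    frames_per_block = 10L), class = "rca_map")
  tc <- roi_timecourse(map, 2, 2)
  expect_equal(tc$mean_rca, rep(0.4, 4))
  expect_equal(tc$sd_rca, rep(0, 4))
  # hand-computed mean/sd convention (sample sd)
  map$rca[1, 2:4, 2:4] <- seq(0.1, 0.9, by = 0.1)
  tc2 <- roi_timecourse(map, 2, 2)
  expect_equal(tc2$mean_rca[1], 0.5)
  expect_equal(tc2$sd_rca[1], sd(seq(0.1, 0.9, by = 0.1)))
  # partial coverage warns with the count
  map$rca[2, 2, 2] <- NA
  expect_warning(roi_timecourse(map, 2, 2), "partial coverage")
  expect_error(roi_timecourse(map, 4, 4), "outside")
})

test_that("exponential decay fitting recovers its own model", {
  t <- seq(0, 20, length.out = 15)
  y <- 0.7 * exp(-0.2 * t)
  fit <- fit_rca_decay(t, y)
  expect_equal(fit$A, 0.7, tolerance = 1e-6)
  expect_equal(fit$k, 0.2, tolerance = 1e-6)
  expect_equal(fit$c, 0, tolerance = 1e-6)
  # A + c equals the fitted value at t = 0
  expect_equal(fit$A + fit$c, fit$fitted[1], tolerance = 1e-9)
  # constant series: k ~ 0 contribution (flat fit)
  fitc <- fit_rca_decay(t, rep(0.55, 15))
  expect_lt(abs(fitc$A) * max(abs(exp(-fitc$k * t) - exp(-fitc$k * t[1]))),
            1e-6)
  expect_equal(fitc$fitted, rep(0.55, 15), tolerance = 1e-6)
  expect_error(fit_rca_decay(t[1:3], y[1:3]), "at least 4")
})

test_that("decay rate is recovered from noisy data at fixed seed", {
  # full-degradation analog: RCA decays to zero, offset-free fit
  set.seed(60)
  t <- seq(0, 19, by = 1)
  y <- 0.7 * exp(-0.25 * t) + rnorm(20, 0, 0.03)
  fit <- fit_rca_decay(t, y, offset = FALSE)
  expect_equal(fit$k, 0.25, tolerance = 0.1)
  expect_true(is.finite(fit$k_se) && fit$k_se > 0)
})

test_that("decaying and constant RCA series give CI-separated rates", {
  # nuclease-active vs inactive condition: the decaying series has a
  # positive rate whose 95% CI excludes both zero and whatever rate the
  # (rate-unidentifiable) constant series reports
  set.seed(61)
  t <- seq(0, 15, length.out = 16)
  decaying <- 0.65 * exp(-0.3 * t) + 0.05 + rnorm(16, 0, 0.03)
  constant <- 0.65 + rnorm(16, 0, 0.03)
  fd <- fit_rca_decay(t, decaying)
  fc <- fit_rca_decay(t, constant)
  ci <- fd$k + c(-1.96, 1.96) * fd$k_se
  expect_gt(ci[1], 0)
  expect_false(fc$k >= ci[1] && fc$k <= ci[2])
  # and the constant series shows no decaying component of any size
  expect_lt(abs(fc$A), 0.05)
})
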