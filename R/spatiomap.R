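#' Tile an image into half-overlapping ROIs
#'
#' Anchors are placed every `roi_size / 2` pixels from 0 to
#' `dim - stride`; windows extending past the edge are truncated to the
#' boundary, so a 1024-px axis with 64-px ROIs yields exactly 32 anchors
#' (the edge windows being stride-wide).
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param roi_size ROI edge length in pixels (even, `>= 16`).
#' @return An `roi_grid`: list with `windows` (list of [roi_window()]s in
#'   row-major grid order), `n_grid_rows`, `n_grid_cols`, `anchor_stride`,
#'   `roi_size`.
#' @export
tile_rois <- function(image_shape, roi_size = 64L) {
  stopifnot(length(image_shape) == 2L)
  if (roi_size %% 2L != 0L || roi_size < 16L)
    stop("roi_size must be an even number >= 16")
  if (any(image_shape < roi_size))
    stop("roi_size exceeds an image dimension")
  stride <- roi_size %/% 2L
  anchors_r <- seq(0L, image_shape[1] - stride, by = stride)
  anchors_c <- seq(0L, image_shape[2] - stride, by = stride)
  windows <- vector("list", length(anchors_r) * length(anchors_c))
  k <- 0L
  for (r in anchors_r) for (cc in anchors_c) {
    k <- k + 1L
    windows[[k]] <- roi_window(r, cc,
                               min(roi_size, image_shape[1] - r),
                               min(roi_size, image_shape[2] - cc))
  }
  structure(list(windows = windows,
                 n_grid_rows = length(anchors_r),
                 n_grid_cols = length(anchors_c),
                 anchor_stride = stride, roi_size = as.integer(roi_size)),
            class = "roi_grid")
}

#' @export
print.roi_grid <- function(x, ...) {
  cat(sprintf("roi_grid: %d x %d windows of %d px (stride %d, half-overlapping)\n",
              x$n_grid_rows, x$n_grid_cols, x$roi_size, x$anchor_stride))
  invisible(x)
}

#' Spatiotemporal RCA map over ROIs and frame blocks
#'
#' For every ROI of the grid and every block of `frames_per_block`
#' consecutive frames, per-frame ACF/ACF/CCF surfaces are computed (about
#' the per-frame ROI mean of the detrended data), averaged over the block,
#' fitted along the fast axis, and combined into RCA.  Low-intensity ROIs
#' (block-mean below `intensity_threshold` times the whole-stack maximum
#' frame mean) and failed fits are marked undefined.
#'
#' @param green,red [image_stack()]s.
#' @param geometry An [acq_geometry()].
#' @param grid An `roi_grid`, or `NULL` to tile with `roi_size`.
#' @param roi_size ROI edge length when `grid` is `NULL`.
#' @param frames_per_block Frames averaged per time block (default 10).
#' @param block_mode `"sliding"` (step 1 frame, smooth movies) or
#'   `"disjoint"` (step `frames_per_block`).
#' @param detrend_window Detrending window, or `NULL` to skip.
#' @param intensity_threshold Fraction of the maximum ROI mean intensity
#'   below which an ROI/block is skipped (default 0.01).
#' @return An `rca_map`: arrays `rca`, `D_g`, `D_r`, `N_g`, `N_r`, `N_c`,
#'   `N_gr` and `status`
#'   (`time_block x grid_row x grid_col`, `NA` = undefined),
#'   `intensity_green`, `intensity_red` (same shape), `block_times`
#'   (seconds, mid-time of each block), `grid`, `frames_per_block`.
#' @export
map_rca <- function(green, red, geometry, grid = NULL, roi_size = 64L,
                    frames_per_block = 10L,
                    block_mode = c("sliding", "disjoint"),
                    detrend_window = 3L, intensity_threshold = 0.01) {
  block_mode <- match.arg(block_mode)
  validate_stack_pair(green, red)
  d <- dim(green$data)
  nf <- d[1]
  if (frames_per_block > nf)
    stop("frames_per_block exceeds the number of frames")
  if (is.null(grid)) grid <- tile_rois(d[2:3], roi_size)
  if (!is.null(detrend_window)) {
    green <- detrend(green, detrend_window)
    red <- detrend(red, detrend_window)
  }
  step <- if (block_mode == "sliding") 1L else frames_per_block
  starts <- seq(1L, nf - frames_per_block + 1L, by = step)
  nb <- length(starts)
  gr <- grid$n_grid_rows; gc <- grid$n_grid_cols
  shape <- c(nb, gr, gc)
  rca <- array(NA_real_, shape); d_g <- rca; d_r <- rca
  n_g <- rca; n_r <- rca; n_c <- rca; n_gr <- rca
  int_g <- rca; int_r <- rca
  status <- array("undefined", shape)
  # reference intensity for the low-signal mask: largest ROI/frame mean
  ref_int <- 0
  roi_means_g <- matrix(0, length(grid$windows), nf)
  roi_means_r <- matrix(0, length(grid$windows), nf)
  for (k in seq_along(grid$windows)) {
    w <- grid$windows[[k]]
    rows <- (w$row_start + 1L):(w$row_start + w$height)
    cols <- (w$col_start + 1L):(w$col_start + w$width)
    roi_means_g[k, ] <- apply(green$data[, rows, cols, drop = FALSE], 1L, mean)
    roi_means_r[k, ] <- apply(red$data[, rows, cols, drop = FALSE], 1L, mean)
  }
  ref_int <- max(roi_means_g, roi_means_r)
  frame_starts <- (seq_len(nf) - 1L) * green$frame_interval
  block_times <- vapply(starts, function(s)
    mean(frame_starts[s:(s + frames_per_block - 1L)]), 0)
  k <- 0L
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    k <- k + 1L
    w <- grid$windows[[k]]
    sub_g <- crop_stack(green, w)
    sub_r <- crop_stack(red, w)
    # per-frame surfaces once, then block averages
    per_frame <- vector("list", nf)
    for (f in seq_len(nf)) {
      fg <- get_frame(sub_g, f); fr <- get_frame(sub_r, f)
      if (mean(fg) <= 0 || mean(fr) <= 0) next
      per_frame[[f]] <- list(
        g = spatial_correlation(fg, fg, "ACF_green", on_constant = "zero"),
        r = spatial_correlation(fr, fr, "ACF_red", on_constant = "zero"),
        c = spatial_correlation(fg, fr, "CCF", on_constant = "zero"))
    }
    for (b in seq_len(nb)) {
      fr_idx <- starts[b]:(starts[b] + frames_per_block - 1L)
      int_g[b, i, j] <- mean(roi_means_g[k, fr_idx])
      int_r[b, i, j] <- mean(roi_means_r[k, fr_idx])
      if (int_g[b, i, j] < intensity_threshold * ref_int ||
          int_r[b, i, j] < intensity_threshold * ref_int) {
        status[b, i, j] <- "low_intensity"; next
      }
      use <- per_frame[fr_idx]
      use <- use[!vapply(use, is.null, TRUE)]
      if (length(use) < 2L) { status[b, i, j] <- "low_intensity"; next }
      res <- tryCatch({
        fit_g <- fit_xi_profile(average_surfaces(lapply(use, `[[`, "g")), geometry)
        fit_r <- fit_xi_profile(average_surfaces(lapply(use, `[[`, "r")), geometry)
        fit_c <- fit_xi_profile(average_surfaces(lapply(use, `[[`, "c")), geometry)
        compute_rca(fit_g, fit_r, fit_c)
      }, error = function(e) NULL)
      if (is.null(res) || res$status != "ok") {
        status[b, i, j] <- "fit_failed"; next
      }
      rca[b, i, j] <- res$RCA
      d_g[b, i, j] <- res$D_g; d_r[b, i, j] <- res$D_r
      n_g[b, i, j] <- res$N_g; n_r[b, i, j] <- res$N_r
      n_c[b, i, j] <- res$N_c; n_gr[b, i, j] <- res$N_gr
      status[b, i, j] <- "ok"
    }
  }
  if (!any(status == "ok"))
    warning("empty map: no ROI/block produced a defined RCA")
  structure(list(rca = rca, D_g = d_g, D_r = d_r,
                 N_g = n_g, N_r = n_r, N_c = n_c, N_gr = n_gr,
                 status = status,
                 intensity_green = int_g, intensity_red = int_r,
                 block_times = block_times, grid = grid,
                 frames_per_block = as.integer(frames_per_block)),
            class = "rca_map")
}

#' @export
print.rca_map <- function(x, ...) {
  cat(sprintf("rca_map: %d blocks x %d x %d ROIs, %d/%d defined, RCA range [%.3g, %.3g]\n",
              dim(x$rca)[1], dim(x$rca)[2], dim(x$rca)[3],
              sum(!is.na(x$rca)), length(x$rca),
              suppressWarnings(min(x$rca, na.rm = TRUE)),
              suppressWarnings(max(x$rca, na.rm = TRUE))))
  invisible(x)
}

# bilinear interpolation from grid anchor centers to pixel coordinates;
# undefined anchors poison their neighborhood (rendered dark, never
# interpolated over)
.interp_grid <- function(values, grid, image_shape) {
  gr <- grid$n_grid_rows; gc <- grid$n_grid_cols
  centers_r <- vapply(seq_len(gr), function(i)
    grid$windows[[(i - 1L) * gc + 1L]]$row_start +
      grid$windows[[(i - 1L) * gc + 1L]]$height / 2, 0)
  centers_c <- vapply(seq_len(gc), function(j)
    grid$windows[[j]]$col_start + grid$windows[[j]]$width / 2, 0)
  px_r <- seq_len(image_shape[1]) - 0.5
  px_c <- seq_len(image_shape[2]) - 0.5
  fi <- findInterval(px_r, centers_r, rightmost.closed = TRUE)
  fj <- findInterval(px_c, centers_c, rightmost.closed = TRUE)
  i0 <- pmin(pmax(fi, 1L), gr - 1L); i1 <- i0 + 1L
  j0 <- pmin(pmax(fj, 1L), gc - 1L); j1 <- j0 + 1L
  tr <- (px_r - centers_r[i0]) / (centers_r[i1] - centers_r[i0])
  tc <- (px_c - centers_c[j0]) / (centers_c[j1] - centers_c[j0])
  tr <- pmin(pmax(tr, 0), 1); tc <- pmin(pmax(tc, 0), 1)
  v00 <- values[cbind(rep(i0, length(px_c)), rep(j0, each = length(px_r)))]
  v01 <- values[cbind(rep(i0, length(px_c)), rep(j1, each = length(px_r)))]
  v10 <- values[cbind(rep(i1, length(px_c)), rep(j0, each = length(px_r)))]
  v11 <- values[cbind(rep(i1, length(px_c)), rep(j1, each = length(px_r)))]
  wr <- rep(tr, length(px_c)); wc <- rep(tc, each = length(px_r))
  out <- (1 - wr) * (1 - wc) * v00 + (1 - wr) * wc * v01 +
    wr * (1 - wc) * v10 + wr * wc * v11
  matrix(out, image_shape[1], image_shape[2])
}

# blue -> cyan -> green -> yellow -> red, low to high
.rca_colormap <- function(v) {
  ramp <- grDevices::colorRamp(c("#0000ff", "#00ffff", "#00ff00",
                                 "#ffff00", "#ff0000"))
  rgb <- ramp(pmin(pmax(v, 0), 1)) / 255
  rgb[!is.finite(rgb)] <- 0
  rgb
}

#' Render an RCA map block as an intensity-modulated RGB image
#'
#' RCA values are bilinearly interpolated from the half-overlapping grid
#' to pixel resolution and mapped to a blue-to-red color scale (high RCA =
#' red); pixel brightness is scaled by the interpolated local mean
#' fluorescence normalized to its maximum.  Pixels whose interpolation
#' neighborhood contains an undefined ROI are rendered dark.
#'
#' @param map An `rca_map`.
#' @param block Block index, or `NULL` for all blocks.
#' @param intensity_channel `"green"` or `"red"` modulation source.
#' @param rca_limits RCA values mapped to the ends of the color scale.
#' @param file Optional PNG path (one file per block; a `%d`-style index
#'   is appended for multiple blocks).
#' @return A `rows x cols x 3` RGB array in `[0, 1]`, or a list of them.
#' @export
render_map <- function(map, block = NULL, intensity_channel = c("green", "red"),
                       rca_limits = c(0, 1), file = NULL) {
  stopifnot(inherits(map, "rca_map"))
  intensity_channel <- match.arg(intensity_channel)
  blocks <- if (is.null(block)) seq_len(dim(map$rca)[1]) else block
  shape <- c(map$grid$anchor_stride * map$grid$n_grid_rows,
             map$grid$anchor_stride * map$grid$n_grid_cols)
  int_arr <- if (intensity_channel == "green") map$intensity_green
             else map$intensity_red
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    rca_b <- matrix(map$rca[b, , ], dim(map$rca)[2], dim(map$rca)[3])
    int_b <- matrix(int_arr[b, , ], dim(map$rca)[2], dim(map$rca)[3])
    rca_px <- .interp_grid(rca_b, map$grid, shape)   # NA where undefined
    int_b[is.na(int_b)] <- 0
    int_px <- .interp_grid(int_b, map$grid, shape)
    int_max <- max(int_px, na.rm = TRUE)
    bright <- if (int_max > 0) pmin(pmax(int_px / int_max, 0), 1) else int_px * 0
    scaled <- (rca_px - rca_limits[1]) / (rca_limits[2] - rca_limits[1])
    dark <- !is.finite(scaled)
    scaled[dark] <- 0
    rgbv <- .rca_colormap(as.vector(scaled))
    bright_v <- as.vector(bright); bright_v[as.vector(dark)] <- 0
    img <- array(rgbv * bright_v, dim = c(shape[1], shape[2], 3L))
    out[[bi]] <- img
    if (!is.null(file)) {
      path <- if (length(blocks) > 1L)
        sprintf("%s_block%03d.png", sub("\\.png$", "", file), b) else file
      grDevices::png(path, width = shape[2], height = shape[1])
      graphics::par(mar = c(0, 0, 0, 0))
      graphics::plot.new()
      graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
      grDevices::dev.off()
    }
  }
  if (length(out) == 1L) out[[1]] else out
}

#' RCA time course over a 3 x 3 block of grid cells
#'
#' Mirrors the white-square region readout: per time block, the mean and
#' (sample) standard deviation of RCA over nine neighboring grid cells.
#'
#' @param map An `rca_map`.
#' @param grid_row,grid_col 1-based grid indices of the top-left cell of
#'   the 3 x 3 selection.
#' @return `data.frame(time, mean_rca, sd_rca, n_defined)`; time in
#'   seconds.  Blocks with fewer than 9 defined cells trigger a
#'   partial-coverage warning and use the defined cells only.
#' @export
roi_timecourse <- function(map, grid_row, grid_col) {
  stopifnot(inherits(map, "rca_map"))
  gr <- dim(map$rca)[2]; gc <- dim(map$rca)[3]
  if (grid_row < 1 || grid_col < 1 || grid_row + 2 > gr || grid_col + 2 > gc)
    stop("3x3 selection falls outside the ROI grid")
  rows <- grid_row:(grid_row + 2L); cols <- grid_col:(grid_col + 2L)
  nb <- dim(map$rca)[1]
  out <- data.frame(time = map$block_times,
                    mean_rca = NA_real_, sd_rca = NA_real_,
                    n_defined = 0L)
  for (b in seq_len(nb)) {
    v <- as.vector(map$rca[b, rows, cols])
    v <- v[!is.na(v)]
    out$n_defined[b] <- length(v)
    if (length(v)) {
      out$mean_rca[b] <- mean(v)
      out$sd_rca[b] <- if (length(v) > 1L) stats::sd(v) else 0
    }
  }
  if (any(out$n_defined < 9L))
    warning(sprintf("partial coverage: %d of %d blocks have fewer than 9 defined cells (min %d)",
                    sum(out$n_defined < 9L), nb, min(out$n_defined)))
  out
}

#' Fit an exponential decay to an RCA time course
#'
#' Fits `RCA(t) = A * exp(-k t) + c` by least squares.  The model is
#' linear in `(A, c)` given `k`, so `k` is searched on a log grid and
#' refined by 1-D optimization with `(A, c)` solved in closed form; a
#' standard error for `k` follows from the Jacobian at the optimum.
#'
#' @param time Time points (minutes by convention; `k` is then 1/min).
#' @param rca RCA values at `time`.
#' @param offset Include the offset `c` (default) or fix `c = 0`.
#' @return A `decay_fit`: `A`, `k`, `c`, `k_se`, `residual`, `fitted`,
#'   `status`.
#' @export
fit_rca_decay <- function(time, rca, offset = TRUE) {
  stopifnot(length(time) == length(rca))
  ok <- is.finite(time) & is.finite(rca)
  time <- time[ok]; rca <- rca[ok]
  if (length(time) < 4L) stop("decay fit needs at least 4 time points")
  t0 <- min(time)
  ts <- time - t0                       # shift so amplitude refers to t = min
  lin_fit <- function(k) {
    if (k == 0 && offset) {
      # A and c are collinear at k = 0: report a pure offset
      fitted <- rep(mean(rca), length(ts))
      return(list(A = 0, c = mean(rca), fitted = fitted,
                  ss = sum((rca - fitted)^2)))
    }
    e <- exp(-k * ts)
    X <- if (offset) cbind(e, 1) else cbind(e)
    cf <- tryCatch(
      suppressWarnings(stats::lsfit(X, rca, intercept = FALSE)$coefficients),
      error = function(err) rep(NA_real_, ncol(X)))
    if (any(!is.finite(cf))) return(list(ss = Inf))
    fitted <- as.vector(X %*% cf)
    list(A = cf[1], c = if (offset) cf[2] else 0, fitted = fitted,
         ss = sum((rca - fitted)^2))
  }
  span <- max(ts) - min(ts)
  ks <- c(0, 10^seq(log10(0.01 / span), log10(100 / span), length.out = 60))
  ss <- vapply(ks, function(k) lin_fit(k)$ss, 0)
  i <- which.min(ss)
  lo <- ks[max(1L, i - 1L)]; hi <- ks[min(length(ks), i + 1L)]
  opt <- stats::optimize(function(k) lin_fit(k)$ss, interval = c(lo, hi),
                         tol = 1e-12)
  k_hat <- if (opt$objective < ss[i]) opt$minimum else ks[i]
  best <- lin_fit(k_hat)
  if (!is.finite(best$ss)) stop("decay fit failed to converge")
  # asymptotic SE of k from the Jacobian of (A, k, c)
  e <- exp(-k_hat * ts)
  J <- cbind(dA = e, dk = -best$A * ts * e, dc = if (offset) rep(1, length(ts)) else NULL)
  p <- ncol(J)
  k_se <- tryCatch({
    sigma2 <- best$ss / max(1L, length(ts) - p)
    sqrt(sigma2 * solve(crossprod(J))["dk", "dk"])
  }, error = function(e) NA_real_)
  structure(list(A = unname(best$A), k = unname(k_hat), c = unname(best$c),
                 k_se = k_se, residual = best$ss,
                 fitted = best$fitted, time = time, t0 = t0,
                 status = "ok"),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: RCA(t) = %.4g * exp(-%.4g t) + %.4g  (k_se = %.3g, SSR = %.3g)\n",
              x$A, x$k, x$c, x$k_se, x$residual))
  invisible(x)
}

#' Export an RCA map as long-format CSV
#'
#' One row per (block, grid_row, grid_col) with RCA, per-channel mean
#' intensity, diffusion coefficients and status.
#'
#' @param map An `rca_map`.
#' @param path Output CSV path.
#' @return The data frame, invisibly (written to `path` if non-NULL).
#' @export
map_to_csv <- function(map, path = NULL) {
  stopifnot(inherits(map, "rca_map"))
  d <- dim(map$rca)
  df <- expand.grid(block = seq_len(d[1]), grid_row = seq_len(d[2]),
                    grid_col = seq_len(d[3]), KEEP.OUT.ATTRS = FALSE)
  df$time_s <- map$block_times[df$block]
  df$rca <- map$rca[as.matrix(df[, 1:3])]
  df$intensity_g <- map$intensity_green[as.matrix(df[, 1:3])]
  df$intensity_r <- map$intensity_red[as.matrix(df[, 1:3])]
  df$D_g <- map$D_g[as.matrix(df[, 1:3])]
  df$D_r <- map$D_r[as.matrix(df[, 1:3])]
  for (f in c("N_g", "N_r", "N_c", "N_gr"))
    if (!is.null(map[[f]])) df[[f]] <- map[[f]][as.matrix(df[, 1:3])]
  df$status <- map$status[as.matrix(df[, 1:3])]
  df <- df[order(df$block, df$grid_row, df$grid_col), ]
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
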