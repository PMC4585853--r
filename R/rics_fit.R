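#' RICS laser-scanning term
#'
#' \deqn{S(\xi, \psi) = \exp\!\left(-\frac{(\delta r\,\xi / w_0)^2 +
#'   (\delta r\,\psi / w_0)^2}{1 + 4 D (\tau_p \xi + \tau_l \psi) /
#'   w_0^2}\right)}
#' accounts for the displacement of the scanning beam between the two
#' pixels of a lag pair.
#'
#' @param xi,psi Pixel lags (vectors recycle).
#' @param geometry An [acq_geometry()].
#' @param D Diffusion coefficient (um^2/s, `>= 0`).
#' @return Values in `(0, 1]`.
#' @export
scan_term <- function(xi, psi, geometry, D) {
  stopifnot(inherits(geometry, "acq_geometry"), D >= 0)
  dr <- geometry$pixel_size; w0 <- geometry$w0
  # correlation depends on the magnitude of the time difference between
  # the two pixels, so negative-lag combinations use |tau|
  tau <- abs(geometry$pixel_dwell * xi + geometry$line_time * psi)
  exp(-((dr * xi / w0)^2 + (dr * psi / w0)^2) / (1 + 4 * D * tau / w0^2))
}

#' RICS 3D free-diffusion term
#'
#' \deqn{G_D(\xi, \psi) = \frac{\gamma}{N}
#'   \left(1 + \frac{4 D (\tau_p \xi + \tau_l \psi)}{w_0^2}\right)^{-1}
#'   \left(1 + \frac{4 D (\tau_p \xi + \tau_l \psi)}{w_z^2}\right)^{-1/2}}
#' where `N` is the mean molecule number in the observation volume.  At
#' zero lag `G_D = gamma / N`.
#'
#' @inheritParams scan_term
#' @param N Mean molecule number (`> 0`).
#' @return Positive values, non-increasing in `tau_p * xi + tau_l * psi`.
#' @export
diffusion_term <- function(xi, psi, geometry, N, D) {
  stopifnot(inherits(geometry, "acq_geometry"), D >= 0)
  if (N <= 0) stop("N must be > 0")
  tau <- abs(geometry$pixel_dwell * xi + geometry$line_time * psi)
  q <- 4 * D * tau
  (geometry$gamma / N) / (1 + q / geometry$w0^2) / sqrt(1 + q / geometry$wz^2)
}

#' Full RICS correlation model G = S * G_D
#'
#' @inheritParams diffusion_term
#' @return Model correlation values.
#' @export
rics_model <- function(xi, psi, geometry, N, D) {
  scan_term(xi, psi, geometry, D) * diffusion_term(xi, psi, geometry, N, D)
}

# unit-amplitude model shape along psi = 0: rics_model with gamma/N == 1
.xi_shape <- function(xi, geometry, D) {
  dr <- geometry$pixel_size; w0 <- geometry$w0
  q <- 4 * D * geometry$pixel_dwell * xi
  exp(-(dr * xi / w0)^2 / (1 + q / w0^2)) / (1 + q / w0^2) /
    sqrt(1 + q / geometry$wz^2)
}

#' Fit the RICS model along the fast-scan axis
#'
#' Extracts the `psi = 0` profile of a correlation surface and fits
#' `G(xi, 0) = S(xi, 0) * G_D(xi, 0)` by least squares with `N` and `D`
#' free (`w0`, `wz`, `gamma` fixed by the geometry).  Because the model is
#' linear in its amplitude `a = gamma / N`, the fit profiles the amplitude
#' out analytically and searches `D` globally on a log grid spanning six
#' decades around the lag-range-matched scale, then refines it by bounded
#' 1-D optimization; this is deterministic and immune to bad starting
#' values.
#'
#' By default ACF fits exclude the zero lag (shot noise is
#' delta-correlated and inflates only `G(0,0)`) and use `xi` in
#' `[1, width/4]`; CCF fits include zero lag (detector noise is
#' independent across channels) and allow a negative fitted amplitude,
#' reported as an `"amplitude_floor"` status so the cross-correlation can
#' be clamped to zero downstream.
#'
#' @param surface A `corr_surface` (its `kind` selects the defaults), or a
#'   `data.frame(xi, G)` profile.
#' @param geometry An [acq_geometry()].
#' @param xi_min,xi_max Fit lag range; defaults per kind as above.
#' @param amplitude `"positive"` restricts `a > 0` (ACF), `"free"` allows
#'   any sign (CCF).  Default chosen from the surface kind.
#' @return A `rics_fit` object: `N`, `D`, `amplitude` (`= gamma / N`),
#'   `residual` (sum of squared residuals), `n_points`, `status`
#'   (`"ok"`, `"amplitude_floor"`, `"failed"`), `kind`.
#' @export
fit_xi_profile <- function(surface, geometry, xi_min = NULL, xi_max = NULL,
                           amplitude = NULL) {
  stopifnot(inherits(geometry, "acq_geometry"))
  if (inherits(surface, "corr_surface")) {
    kind <- surface$kind
    if (is.null(amplitude)) amplitude <- if (kind == "CCF") "free" else "positive"
    if (is.null(xi_min)) xi_min <- if (kind == "CCF") 0L else 1L
    if (is.null(xi_max)) xi_max <- max(surface$xi_lags)
    prof <- xi_profile(surface, xi_min = xi_min, xi_max = xi_max)
  } else {
    kind <- "profile"
    if (is.null(amplitude)) amplitude <- "positive"
    prof <- surface
    if (!is.null(xi_min)) prof <- prof[prof$xi >= xi_min, ]
    if (!is.null(xi_max)) prof <- prof[prof$xi <= xi_max, ]
  }
  amplitude <- match.arg(amplitude, c("positive", "free"))
  xi <- prof$xi; G <- prof$G
  ok <- is.finite(G)
  xi <- xi[ok]; G <- G[ok]
  failed <- function(msg) structure(
    list(N = NA_real_, D = NA_real_, amplitude = NA_real_,
         residual = NA_real_, n_points = length(G), status = "failed",
         message = msg, kind = kind, geometry = geometry),
    class = "rics_fit")
  if (length(G) < 8L) return(failed("fewer than 8 usable lags"))
  if (all(G == 0)) return(failed("all-zero profile"))

  # profile the amplitude: for fixed D, a*(D) = <u,G>/<u,u>, u = unit shape
  prof_fit <- function(log10D) {
    u <- .xi_shape(xi, geometry, 10^log10D)
    a <- sum(u * G) / sum(u * u)
    if (amplitude == "positive" && a <= 0) a <- NA_real_
    ss <- if (is.na(a)) sum(G^2) + 1 else sum((G - a * u)^2)
    list(a = a, ss = ss)
  }
  # grid centered on the D for which the diffusion decay spans the range
  d_star <- geometry$w0^2 / (4 * geometry$pixel_dwell * max(xi, 1))
  grid <- log10(d_star) + seq(-4, 4, by = 0.25)
  ss <- vapply(grid, function(g) prof_fit(g)$ss, 0)
  i <- which.min(ss)
  opt <- stats::optimize(function(g) prof_fit(g)$ss,
                         interval = c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                         tol = 1e-10)
  cand <- list(list(log10D = opt$minimum, ss = opt$objective),
               list(log10D = grid[i], ss = ss[i]))
  # D = 0 boundary (no decay: pure scanning term)
  u0 <- .xi_shape(xi, geometry, 0)
  a0 <- sum(u0 * G) / sum(u0 * u0)
  if (!(amplitude == "positive" && a0 <= 0))
    cand <- c(cand, list(list(log10D = -Inf, ss = sum((G - a0 * u0)^2))))
  best <- cand[[which.min(vapply(cand, `[[`, 0, "ss"))]]
  D_hat <- if (is.finite(best$log10D)) 10^best$log10D else 0
  u <- .xi_shape(xi, geometry, D_hat)
  a_hat <- sum(u * G) / sum(u * u)
  if (amplitude == "positive" && a_hat <= 0)
    return(failed("no positive-amplitude solution"))
  status <- if (a_hat <= 0) "amplitude_floor" else "ok"
  structure(
    list(N = if (a_hat > 0) geometry$gamma / a_hat else Inf,
         D = D_hat, amplitude = a_hat,
         residual = sum((G - a_hat * u)^2), n_points = length(G),
         status = status, message = NULL, kind = kind, geometry = geometry),
    class = "rics_fit")
}

#' @export
print.rics_fit <- function(x, ...) {
  cat(sprintf("rics_fit [%s, %s]: N = %.4g, D = %.4g um^2/s, amplitude = %.4g, SSR = %.3g (%d lags)\n",
              x$kind, x$status, x$N, x$D, x$amplitude, x$residual, x$n_points))
  invisible(x)
}

#' Combine per-channel and cross fits into molecule numbers and RCA
#'
#' The apparent cross-correlation molecule number `N_c` follows from the
#' cross amplitude `G_c(0,0) = gamma / N_c`; with
#' `G_c(0,0) = gamma * N_gr / (N_g * N_r)` this gives the double-labeled
#' number `N_gr = N_g * N_r / N_c` and the relative cross-correlation
#' amplitude `RCA = N_gr / N_g = N_r / N_c`, the fraction of green-labeled
#' molecules that also carry the red label.  A non-positive cross
#' amplitude means no coincident species: RCA = 0.
#'
#' @param fit_g,fit_r,fit_c `rics_fit` results for the green ACF, red ACF
#'   and CCF.
#' @return A `cross_corr_result`: `N_g`, `N_r`, `N_c`, `N_gr`, `RCA`,
#'   `D_g`, `D_r`, `status`.
#' @export
compute_rca <- function(fit_g, fit_r, fit_c) {
  for (f in list(fit_g, fit_r, fit_c))
    if (!inherits(f, "rics_fit")) stop("inputs must be rics_fit objects")
  if (fit_g$status == "failed" || fit_r$status == "failed" ||
      fit_c$status == "failed") {
    return(structure(list(N_g = fit_g$N, N_r = fit_r$N, N_c = fit_c$N,
                          N_gr = NA_real_, RCA = NA_real_,
                          D_g = fit_g$D, D_r = fit_r$D, status = "failed"),
                     class = "cross_corr_result"))
  }
  gamma <- fit_c$geometry$gamma
  a_c <- fit_c$amplitude
  if (!is.finite(a_c) || a_c <= 0) {
    n_c <- Inf; n_gr <- 0; rca <- 0
  } else {
    n_c <- gamma / a_c
    n_gr <- fit_g$N * fit_r$N / n_c
    rca <- max(0, n_gr / fit_g$N)
  }
  structure(list(N_g = fit_g$N, N_r = fit_r$N, N_c = n_c, N_gr = n_gr,
                 RCA = rca, D_g = fit_g$D, D_r = fit_r$D, status = "ok"),
            class = "cross_corr_result")
}

#' @export
print.cross_corr_result <- function(x, ...) {
  cat(sprintf("ccRICS result [%s]: N_g = %.4g, N_r = %.4g, N_c = %.4g, N_gr = %.4g\n",
              x$status, x$N_g, x$N_r, x$N_c, x$N_gr))
  cat(sprintf("  RCA = %.4g   (D_g = %.4g, D_r = %.4g um^2/s)\n",
              x$RCA, x$D_g, x$D_r))
  invisible(x)
}

#' Whole-field ccRICS analysis of a stack pair
#'
#' Runs the full single-ROI pipeline: optional detrending, per-frame
#' ACF/ACF/CCF surfaces averaged over all frames, fast-axis fits, and RCA.
#'
#' @param green,red [image_stack()]s (validated as a pair).
#' @param geometry An [acq_geometry()].
#' @param detrend_window Frames in the detrending moving average, or
#'   `NULL` to skip detrending (homogeneous samples).
#' @param max_lag_xi Largest fitted/computed `xi` lag (default width/4).
#' @return A `cross_corr_result` with the three averaged surfaces attached
#'   as `surfaces` and fits as `fits`.
#' @export
ccrics_analysis <- function(green, red, geometry, detrend_window = 3L,
                            max_lag_xi = NULL) {
  validate_stack_pair(green, red)
  if (!is.null(detrend_window)) {
    green <- detrend(green, detrend_window)
    red <- detrend(red, detrend_window)
  }
  s_g <- stack_correlation(green, kind = "ACF_green", max_lag_xi = max_lag_xi)
  s_r <- stack_correlation(red, kind = "ACF_red", max_lag_xi = max_lag_xi)
  s_c <- stack_correlation(green, red, kind = "CCF", max_lag_xi = max_lag_xi)
  fit_g <- fit_xi_profile(s_g, geometry)
  fit_r <- fit_xi_profile(s_r, geometry)
  fit_c <- fit_xi_profile(s_c, geometry)
  res <- compute_rca(fit_g, fit_r, fit_c)
  res$surfaces <- list(ACF_green = s_g, ACF_red = s_r, CCF = s_c)
  res$fits <- list(green = fit_g, red = fit_r, cross = fit_c)
  res
}
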