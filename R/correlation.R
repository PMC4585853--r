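#' Spatial correlation surfaces
#'
#' `spatial_correlation()` computes the 2D spatial correlation
#' \deqn{G(\xi, \psi) = \frac{\langle \delta I_a(x, y)\,
#'   \delta I_b(x + \xi, y + \psi) \rangle}{\langle I_a \rangle
#'   \langle I_b \rangle}}
#' between two images over pixel lags \eqn{\xi} (fast/column axis) and
#' \eqn{\psi} (slow/row axis).  The estimator is linear (zero-padded FFT,
#' no wrap-around); each lag is normalized by its overlap pixel count
#' before division by the product of means.  `a == b` yields an ACF,
#' distinct images a CCF.
#'
#' @param a,b Numeric matrices of identical shape with positive means.
#' @param kind Surface kind label: `"ACF_green"`, `"ACF_red"` or `"CCF"`.
#' @param max_lag_xi,max_lag_psi Largest lag retained per axis; defaults
#'   to a quarter of the corresponding image dimension.
#' @param on_constant What to do when an image has zero variance:
#'   `"error"` (default) or `"zero"` (return an all-zero surface).
#' @return A `corr_surface`: list with matrix `G` (rows = \eqn{\psi} lags,
#'   columns = \eqn{\xi} lags), `xi_lags`, `psi_lags`, `kind`,
#'   `n_frames_averaged`.
#' @examples
#' img <- matrix(0, 4, 4); img[2, 3] <- 16
#' s <- spatial_correlation(img, img, "ACF_green")
#' s$G[s$psi_lags == 0, s$xi_lags == 0]  # 15
#' @export
spatial_correlation <- function(a, b = a, kind = c("ACF_green", "ACF_red", "CCF"),
                                max_lag_xi = NULL, max_lag_psi = NULL,
                                on_constant = c("error", "zero")) {
  kind <- match.arg(kind)
  on_constant <- match.arg(on_constant)
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  M <- nrow(a); N <- ncol(a)
  ma <- mean(a); mb <- mean(b)
  if (ma <= 0 || mb <= 0)
    stop("degenerate input: image mean must be > 0 (empty or masked ROI?)")
  if (is.null(max_lag_xi)) max_lag_xi <- N %/% 4L
  if (is.null(max_lag_psi)) max_lag_psi <- M %/% 4L
  if (max_lag_xi >= N || max_lag_psi >= M) stop("lag range exceeds image size")
  xi <- -max_lag_xi:max_lag_xi
  psi <- -max_lag_psi:max_lag_psi
  da <- a - ma; db <- b - mb
  if (all(da == 0) || all(db == 0)) {
    if (on_constant == "error")
      stop("degenerate input: image has no fluctuations (constant intensity)")
    G <- matrix(0, length(psi), length(xi))
  } else {
    P <- 2L * M; Q <- 2L * N
    A <- matrix(0, P, Q); A[1:M, 1:N] <- da
    B <- matrix(0, P, Q); B[1:M, 1:N] <- db
    cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) / (P * Q)
    idx <- function(k, n) (k %% n) + 1L
    G <- cc[idx(psi, P), idx(xi, Q), drop = FALSE]
    overlap <- outer(M - abs(psi), N - abs(xi))
    G <- G / overlap / (ma * mb)
  }
  dimnames(G) <- list(psi = psi, xi = xi)
  structure(list(G = G, xi_lags = xi, psi_lags = psi, kind = kind,
                 n_frames_averaged = 1L),
            class = "corr_surface")
}

#' @export
print.corr_surface <- function(x, ...) {
  cat(sprintf("corr_surface [%s]: psi in [%d, %d], xi in [%d, %d], %d frame(s) averaged, G(0,0) = %.4g\n",
              x$kind, min(x$psi_lags), max(x$psi_lags),
              min(x$xi_lags), max(x$xi_lags), x$n_frames_averaged,
              x$G[x$psi_lags == 0, x$xi_lags == 0]))
  invisible(x)
}

#' Heat-map display of a correlation surface
#'
#' @param x A `corr_surface`.
#' @param zlim Color range (defaults to the finite data range).
#' @param ... Passed to [graphics::image()].
#' @export
plot.corr_surface <- function(x, zlim = NULL, ...) {
  z <- t(x$G)  # image() wants x = first index; use xi horizontally
  if (is.null(zlim)) zlim <- range(z[is.finite(z)])
  graphics::image(x = x$xi_lags, y = x$psi_lags, z = z, zlim = zlim,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = expression(xi ~ "(pixels)"),
                  ylab = expression(psi ~ "(lines)"),
                  main = x$kind, useRaster = TRUE, ...)
  invisible(x)
}

#' Average correlation surfaces element-wise
#'
#' Per-frame surfaces are averaged (typically over 10 frames) before
#' fitting; inputs must share kind and lag axes.
#'
#' @param surfaces List of `corr_surface` objects.
#' @return A `corr_surface` with `n_frames_averaged` summed.
#' @export
average_surfaces <- function(surfaces) {
  if (inherits(surfaces, "corr_surface")) surfaces <- list(surfaces)
  if (!length(surfaces)) stop("no surfaces to average")
  ref <- surfaces[[1]]
  for (s in surfaces) {
    if (!inherits(s, "corr_surface")) stop("inputs must be corr_surface objects")
    if (s$kind != ref$kind) stop("cannot average surfaces of mixed kinds")
    if (!identical(s$xi_lags, ref$xi_lags) || !identical(s$psi_lags, ref$psi_lags))
      stop("cannot average surfaces with mismatched lag axes")
  }
  out <- ref
  out$G <- Reduce(`+`, lapply(surfaces, `[[`, "G")) / length(surfaces)
  out$n_frames_averaged <- sum(vapply(surfaces, `[[`, 1L, "n_frames_averaged"))
  out
}

#' Frame-averaged correlation surface of a stack (or stack pair)
#'
#' Computes one surface per frame about the per-frame spatial mean, then
#' averages.  Frames whose mean falls below `min_mean` are skipped.
#'
#' @param stack_a An [image_stack()] (or plain array).
#' @param stack_b Second stack for a CCF, or `NULL` for the ACF of
#'   `stack_a`.
#' @param kind Surface kind; defaults to `"CCF"` when `stack_b` is given,
#'   else to the ACF of `stack_a`'s channel.
#' @param frames Frame indices to use (default all).
#' @param min_mean Minimum usable frame mean (absolute counts).
#' @inheritParams spatial_correlation
#' @return A `corr_surface`, or `NULL` if no frame was usable.
#' @export
stack_correlation <- function(stack_a, stack_b = NULL, kind = NULL,
                              frames = NULL, max_lag_xi = NULL,
                              max_lag_psi = NULL, min_mean = 0) {
  da <- if (inherits(stack_a, "image_stack")) stack_a$data else stack_a
  db <- if (is.null(stack_b)) NULL
        else if (inherits(stack_b, "image_stack")) stack_b$data else stack_b
  if (is.null(kind)) {
    kind <- if (!is.null(db)) "CCF"
            else if (inherits(stack_a, "image_stack") && stack_a$channel == "red")
              "ACF_red" else "ACF_green"
  }
  d <- dim(da)
  if (is.null(frames)) frames <- seq_len(d[1])
  surfaces <- list()
  for (f in frames) {
    fa <- matrix(da[f, , ], d[2], d[3])
    fb <- if (is.null(db)) fa else matrix(db[f, , ], d[2], d[3])
    if (mean(fa) <= min_mean || mean(fb) <= min_mean) next
    surfaces[[length(surfaces) + 1L]] <-
      spatial_correlation(fa, fb, kind = kind, max_lag_xi = max_lag_xi,
                          max_lag_psi = max_lag_psi, on_constant = "zero")
  }
  if (!length(surfaces)) return(NULL)
  average_surfaces(surfaces)
}

#' Extract the fast-axis profile G(xi, psi = 0)
#'
#' @param surface A `corr_surface`.
#' @param xi_min,xi_max Lag range (non-negative side).
#' @param fold Average `G(xi)` with `G(-xi)` where both exist (reduces
#'   estimator noise; surfaces are symmetric in expectation).
#' @return `data.frame(xi, G)`.
#' @export
xi_profile <- function(surface, xi_min = 0L, xi_max = NULL, fold = TRUE) {
  stopifnot(inherits(surface, "corr_surface"))
  if (is.null(xi_max)) xi_max <- max(surface$xi_lags)
  xi <- xi_min:xi_max
  row <- surface$G[surface$psi_lags == 0L, , drop = TRUE]
  pos <- row[match(xi, surface$xi_lags)]
  if (fold) {
    neg <- row[match(-xi, surface$xi_lags)]
    ok <- !is.na(neg) & xi > 0L
    pos[ok] <- (pos[ok] + neg[ok]) / 2
  }
  data.frame(xi = xi, G = pos)
}

#' Write a correlation surface as long-format CSV (xi, psi, G)
#'
#' @param surface A `corr_surface`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "corr_surface"))
  df <- expand.grid(psi = surface$psi_lags, xi = surface$xi_lags,
                    KEEP.OUT.ATTRS = FALSE)
  df$G <- as.vector(surface$G)
  df <- df[, c("xi", "psi", "G")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
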