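#' Specify a diffusing emitter species for the simulator
#'
#' @param label_mode One of `"green_only"`, `"red_only"`, `"double"`.
#'   Double-labeled particles contribute to both channels from identical
#'   positions, emulating an intact dual-labeled probe.
#' @param n_particles Number of particles of this species in the box.
#' @param D Diffusion coefficient in um^2/s (`>= 0`; 0 pins particles).
#' @param brightness Expected photon counts per pixel dwell for a particle
#'   at the focal center, per labeled channel.  A length-2 vector
#'   `c(green, red)` sets the channels separately for double labels.
#' @param positions Optional `n_particles x 3` matrix of starting
#'   positions (um, scan coordinates: x along columns, y along rows, z
#'   axial with the focal plane at 0).  Default: uniform in the box.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(label_mode = c("double", "green_only", "red_only"),
                         n_particles, D, brightness = 5, positions = NULL) {
  label_mode <- match.arg(label_mode)
  if (n_particles < 0) stop("n_particles must be >= 0")
  if (D < 0) stop("D must be >= 0")
  if (any(!is.finite(brightness)) || any(brightness < 0))
    stop("brightness must be finite and >= 0")
  if (length(brightness) == 1L) brightness <- c(brightness, brightness)
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != n_particles || ncol(positions) != 3L)
      stop("positions must be an n_particles x 3 matrix")
  }
  structure(list(label_mode = label_mode,
                 n_particles = as.integer(n_particles),
                 D = as.numeric(D),
                 brightness = as.numeric(brightness[1:2]),
                 positions = positions),
            class = "species_spec")
}

#' Configure a dual-channel raster-scan simulation
#'
#' The simulation box is periodic and centered laterally on the scanned
#' field, axially on the focal plane.  By default it covers the scan area
#' with a margin of `2 * w0` on each side laterally and spans `4 * wz`
#' axially, the minimum for a stationary concentration around the
#' observation volume.
#'
#' @param geometry An [acq_geometry()].
#' @param species List of [species_spec()] objects.
#' @param n_frames Number of frames to scan.
#' @param box Box dimensions `c(x, y, z)` in um, or `NULL` for the default.
#'   Must be at least `4 * w0` laterally and `4 * wz` axially.
#' @param background Mean background counts per pixel, `c(green, red)` (a
#'   scalar is used for both).
#' @param crosstalk Fraction of the green-channel signal leaking into the
#'   red channel (default 0).
#' @param frame_interval Time between frame starts in seconds; must be at
#'   least `n_rows * line_time`.  Default: no inter-frame gap.
#' @param seed RNG seed; a fixed seed makes the output bit-reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(geometry, species, n_frames, box = NULL,
                       background = 0.5, crosstalk = 0,
                       frame_interval = NULL, seed = 1L) {
  stopifnot(inherits(geometry, "acq_geometry"))
  if (inherits(species, "species_spec")) species <- list(species)
  if (!length(species) || !all(vapply(species, inherits, TRUE, "species_spec")))
    stop("species must be a list of species_spec objects")
  if (n_frames < 1) stop("n_frames must be >= 1")
  scan_x <- (geometry$n_cols - 1) * geometry$pixel_size
  scan_y <- (geometry$n_rows - 1) * geometry$pixel_size
  if (is.null(box))
    box <- c(scan_x + 4 * geometry$w0, scan_y + 4 * geometry$w0,
             4 * geometry$wz)
  if (length(box) != 3L || any(box <= 0)) stop("box must be positive c(x, y, z)")
  if (box[1] < 4 * geometry$w0 || box[2] < 4 * geometry$w0)
    stop("box too small: lateral dimensions must be >= 4 * w0")
  if (box[3] < 4 * geometry$wz)
    stop("box too small: axial dimension must be >= 4 * wz")
  if (length(background) == 1L) background <- c(background, background)
  if (any(background < 0)) stop("background must be >= 0")
  if (crosstalk < 0 || crosstalk > 1) stop("crosstalk must lie in [0, 1]")
  frame_time <- geometry$n_rows * geometry$line_time
  if (is.null(frame_interval)) frame_interval <- frame_time
  if (frame_interval < frame_time - 1e-12)
    stop("frame_interval must be >= n_rows * line_time")
  structure(list(geometry = geometry, species = species,
                 n_frames = as.integer(n_frames), box = as.numeric(box),
                 background = as.numeric(background[1:2]),
                 crosstalk = as.numeric(crosstalk),
                 frame_interval = as.numeric(frame_interval),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected in-focus molecule number for a simulation configuration
#'
#' The `N` recovered by a fit of `G(0,0) = gamma / N` is the occupancy of
#' the gamma-weighted focal volume: for a 3D Gaussian PSF,
#' `G(0,0) = 1 / (c * pi^{3/2} * w0^2 * wz)` with `c` the number density,
#' so `N = gamma * c * pi^{3/2} * w0^2 * wz`
#' (`= c * (pi/2)^{3/2} w0^2 wz` at the ideal `gamma = 2^{-3/2}`).
#' Uniform background dilutes the measured amplitude by the squared
#' signal fraction and inflates apparent `N` accordingly; the expectation
#' returned here is for background-free data.
#'
#' @param config A `sim_config`.
#' @param channel `"green"` or `"red"`.
#' @return Named numbers: `N` for the channel, `N_double` from
#'   double-labeled species only.
#' @export
expected_focal_number <- function(config, channel = c("green", "red")) {
  channel <- match.arg(channel)
  v_box <- prod(config$box)
  v_eff <- config$geometry$gamma * pi^1.5 * config$geometry$w0^2 *
    config$geometry$wz
  keep <- switch(channel,
                 green = c("green_only", "double"),
                 red = c("red_only", "double"))
  n_lab <- sum(vapply(config$species, function(s)
    if (s$label_mode %in% keep) s$n_particles else 0L, 0))
  n_dbl <- sum(vapply(config$species, function(s)
    if (s$label_mode == "double") s$n_particles else 0L, 0))
  c(N = n_lab / v_box * v_eff, N_double = n_dbl / v_box * v_eff)
}

#' Simulate a dual-channel raster-scanned image stack
#'
#' Each pixel value is Poisson-distributed with mean
#' `background + sum over particles of brightness * PSF(position at the
#' pixel's scan time - pixel center)`, with the 3D Gaussian PSF
#' `exp(-2 (x^2 + y^2) / w0^2) * exp(-2 z^2 / wz^2)`.  Particle paths are
#' Brownian with per-tick Gaussian increments of variance `2 D dt` per
#' axis and periodic wrapping; double-labeled particles illuminate both
#' channels from identical positions.
#'
#' @param config A [sim_config()].
#' @param return_noiseless If `TRUE`, the pre-Poisson intensity fields are
#'   returned alongside the sampled stacks (for oracle tests).
#' @return A list with `green` and `red` [image_stack()]s, a `truth`
#'   record (configured N, D, double-labeled fraction, expected focal
#'   occupancies), and optionally `noiseless` arrays.
#' @export
simulate_stack <- function(config, return_noiseless = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$geometry
  set.seed(config$seed)
  scan_x <- (g$n_cols - 1) * g$pixel_size
  scan_y <- (g$n_rows - 1) * g$pixel_size
  origin <- c(scan_x / 2 - config$box[1] / 2,
              scan_y / 2 - config$box[2] / 2,
              -config$box[3] / 2)
  npx <- config$n_frames * g$n_rows * g$n_cols
  green <- numeric(npx); red <- numeric(npx)
  for (s in config$species) {
    if (s$n_particles == 0L) next
    pos0 <- if (!is.null(s$positions)) s$positions else
      cbind(stats::runif(s$n_particles, origin[1], origin[1] + config$box[1]),
            stats::runif(s$n_particles, origin[2], origin[2] + config$box[2]),
            stats::runif(s$n_particles, origin[3], origin[3] + config$box[3]))
    psf <- scan_species_cpp(config$n_frames, g$n_rows, g$n_cols,
                            g$pixel_dwell, g$line_time, config$frame_interval,
                            g$pixel_size, g$w0, g$wz, pos0, s$D,
                            origin, config$box)
    if (s$label_mode %in% c("green_only", "double"))
      green <- green + s$brightness[1] * psf
    if (s$label_mode %in% c("red_only", "double"))
      red <- red + s$brightness[2] * psf
  }
  if (config$crosstalk > 0) red <- red + config$crosstalk * green
  green <- green + config$background[1]
  red <- red + config$background[2]
  # tick order is (col fastest, then row, then frame); reshape to (f, r, c)
  to_stack <- function(v) {
    aperm(array(v, dim = c(g$n_cols, g$n_rows, config$n_frames)), c(3, 2, 1))
  }
  g_noiseless <- to_stack(green)
  r_noiseless <- to_stack(red)
  g_counts <- array(stats::rpois(npx, g_noiseless), dim = dim(g_noiseless))
  r_counts <- array(stats::rpois(npx, r_noiseless), dim = dim(r_noiseless))
  frac <- {
    ng <- sum(vapply(config$species, function(s)
      if (s$label_mode %in% c("green_only", "double")) s$n_particles else 0L, 0))
    nd <- sum(vapply(config$species, function(s)
      if (s$label_mode == "double") s$n_particles else 0L, 0))
    if (ng > 0) nd / ng else NA_real_
  }
  out <- list(
    green = image_stack(g_counts, "green", config$frame_interval),
    red = image_stack(r_counts, "red", config$frame_interval),
    truth = list(
      species = config$species,
      double_fraction = frac,
      N_green = unname(expected_focal_number(config, "green")["N"]),
      N_red = unname(expected_focal_number(config, "red")["N"]),
      N_double = unname(expected_focal_number(config, "green")["N_double"]),
      seed = config$seed))
  if (return_noiseless)
    out$noiseless <- list(green = g_noiseless, red = r_noiseless)
  out
}

#' Sample Brownian particle paths on the pixel-time lattice
#'
#' Reference-path generator used for diffusion-statistics tests: positions
#' are a cumulative sum of independent Gaussian increments with per-axis
#' variance `2 D dt` per tick, wrapped periodically into the box.
#'
#' @param n Number of particles.
#' @param D Diffusion coefficient (um^2/s).
#' @param box Box dimensions `c(x, y, z)` in um.
#' @param n_ticks Number of time steps.
#' @param seed RNG seed.
#' @param dt Tick duration in seconds; a scalar, or a vector of length
#'   `n_ticks` for a non-uniform lattice (flyback, frame gaps).
#' @param wrap Apply periodic wrapping (`FALSE` returns free paths, useful
#'   for mean-square-displacement checks).
#' @return Array `(n_ticks + 1, 3, n)` of positions; paths start at the
#'   box center.
#' @export
particle_paths <- function(n, D, box, n_ticks, seed = 1L, dt = 1e-5,
                           wrap = TRUE) {
  if (n < 1) stop("n must be >= 1")
  if (D < 0) stop("D must be >= 0")
  if (length(dt) == 1L) dt <- rep(dt, n_ticks)
  if (length(dt) != n_ticks) stop("dt must be a scalar or length n_ticks")
  set.seed(seed)
  out <- array(0, dim = c(n_ticks + 1L, 3L, n))
  sd_tick <- sqrt(2 * D * dt)
  for (p in seq_len(n)) {
    steps <- matrix(stats::rnorm(3L * n_ticks), n_ticks, 3L) * sd_tick
    path <- rbind(0, apply(steps, 2L, cumsum))
    if (wrap)
      for (ax in 1:3) path[, ax] <- (path[, ax] + box[ax] / 2) %% box[ax] - box[ax] / 2
    out[, , p] <- path
  }
  out
}

#' Simulation protocol mirroring the in-solution probe measurements
#'
#' 50 frames of 256 x 256 px over 385 s with the [default_geometry()],
#' 100 diffusing particles at `D = 100` um^2/s.  `fraction_double = 1`
#' gives the intact double-labeled probe; `fraction_double = 0` gives the
#' negative control, where the green and red labels sit on independent
#' single-labeled particles (100 of each).
#'
#' @param fraction_double Fraction of green-labeled particles that also
#'   carry the red label, in `[0, 1]`.
#' @param n_particles Green-labeled particle count (matched by the
#'   red-labeled count).
#' @param D Diffusion coefficient (um^2/s).
#' @param n_frames,n_rows,n_cols Stack dimensions.
#' @param total_time Total acquisition time in seconds (sets the frame
#'   interval).
#' @param brightness,background Counts per dwell at focus / per pixel.
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
solution_protocol <- function(fraction_double = 1, n_particles = 100,
                              D = 100, n_frames = 50, n_rows = 256L,
                              n_cols = 256L, total_time = 385,
                              brightness = 5, background = 0.5, seed = 1L) {
  stopifnot(fraction_double >= 0, fraction_double <= 1)
  n_dbl <- round(fraction_double * n_particles)
  n_single <- n_particles - n_dbl
  species <- list()
  if (n_dbl > 0)
    species <- c(species, list(species_spec("double", n_dbl, D, brightness)))
  if (n_single > 0)
    species <- c(species,
                 list(species_spec("green_only", n_single, D, brightness),
                      species_spec("red_only", n_single, D, brightness)))
  sim_config(default_geometry(n_rows, n_cols), species, n_frames = n_frames,
             background = background, frame_interval = total_time / n_frames,
             seed = seed)
}
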