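#' A single-channel time-lapse image stack
#'
#' Wraps a `frames x rows x cols` array of non-negative intensities with a
#' channel label and the frame interval.  Raw input is expected to be
#' photon-count-like integers; detrended stacks hold floating values but
#' stay non-negative on average.
#'
#' @param data Numeric array indexed `(frame, row, col)`, all values finite
#'   and `>= 0`.  A matrix is promoted to a single-frame stack.
#' @param channel Channel label, `"green"` or `"red"`.
#' @param frame_interval Time between frame starts in seconds.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, channel = c("green", "red"),
                        frame_interval = 1) {
  channel <- match.arg(channel)
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a (frame, row, col) array")
  if (!all(is.finite(data)))
    stop("stack contains non-finite values")
  if (any(data < 0))
    stop("stack contains negative values")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  structure(list(data = data, channel = channel,
                 frame_interval = as.numeric(frame_interval)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack [%s]: %d frames of %d x %d px, dt = %.4g s, mean = %.4g\n",
              x$channel, d[1], d[2], d[3], x$frame_interval, mean(x$data)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1L]

#' Extract a single frame as a rows x cols matrix
#' @param stack An `image_stack`.
#' @param frame Frame index (1-based).
#' @return A numeric matrix.
#' @export
get_frame <- function(stack, frame) {
  d <- dim(stack$data)
  if (frame < 1 || frame > d[1]) stop("frame index out of range")
  matrix(stack$data[frame, , ], d[2], d[3])
}

#' Crop a stack to a rectangular ROI window
#'
#' @param stack An `image_stack`.
#' @param window An `roi_window` (see [roi_window()]).
#' @return An `image_stack` restricted to the window.
#' @export
crop_stack <- function(stack, window) {
  d <- dim(stack$data)
  rows <- (window$row_start + 1L):(window$row_start + window$height)
  cols <- (window$col_start + 1L):(window$col_start + window$width)
  if (max(rows) > d[2] || max(cols) > d[3])
    stop("ROI window exceeds image bounds")
  out <- stack
  out$data <- stack$data[, rows, cols, drop = FALSE]
  out
}

#' Rectangular region of interest
#'
#' Coordinates are 0-based and inclusive of the start pixel; the window
#' spans `height` rows and `width` columns.
#'
#' @param row_start,col_start 0-based pixel indices of the top-left corner.
#' @param height,width Window extent in pixels; each must be `>= 8` so the
#'   fit has a usable lag range.
#' @return An object of class `roi_window`.
#' @export
roi_window <- function(row_start, col_start, height, width) {
  if (row_start < 0 || col_start < 0) stop("window start must be >= 0")
  if (height < 8 || width < 8) stop("ROI windows must be at least 8 px")
  structure(list(row_start = as.integer(row_start),
                 col_start = as.integer(col_start),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_window")
}

#' Validate a green/red channel pair
#'
#' Confirms that both stacks have identical frame counts and frame shapes
#' and contain only finite non-negative values; errors name the offending
#' axis.
#'
#' @param green,red `image_stack` objects.
#' @return Invisibly, `list(green =, red =)` when valid.
#' @export
validate_stack_pair <- function(green, red) {
  stopifnot(inherits(green, "image_stack"), inherits(red, "image_stack"))
  dg <- dim(green$data); dr <- dim(red$data)
  if (dg[1] != dr[1])
    stop(sprintf("frame-count mismatch: green has %d frames, red has %d",
                 dg[1], dr[1]))
  if (dg[2] != dr[2] || dg[3] != dr[3])
    stop(sprintf("shape mismatch: green frames are %dx%d, red frames are %dx%d",
                 dg[2], dg[3], dr[2], dr[3]))
  if (any(green$data < 0)) stop("negative values in green stack")
  if (any(red$data < 0)) stop("negative values in red stack")
  invisible(list(green = green, red = red))
}
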