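# Minimal baseline TIFF 6.0 I/O (uncompressed, grayscale, multi-page).
# No TIFF package ships with this toolchain, so the subset needed for
# photon-count stacks is implemented here: little- or big-endian reading,
# uint8/16/32 and float32/64 samples, strip layout, and an optional
# 2-sample-per-pixel dual-channel split.  The writer emits little-endian,
# single-strip pages (uint16/uint32 for integer data, float64 otherwise).

.tiff_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L, FLOAT = 11L, DOUBLE = 12L)
.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L,
                     `12` = 8L, `16` = 8L, `17` = 8L)

.rd_int <- function(raw, off, size, endian, signed = FALSE) {
  v <- readBin(raw[(off + 1):(off + size)], "integer", n = 1L, size = size,
               endian = endian, signed = signed || size == 4L)
  if (!signed && size == 4L && v < 0) v <- v + 2^32
  v
}

.rd_entry_values <- function(raw, entry_off, endian) {
  tag <- .rd_int(raw, entry_off, 2L, endian)
  type <- .rd_int(raw, entry_off + 2L, 2L, endian)
  count <- .rd_int(raw, entry_off + 4L, 4L, endian)
  size <- .tiff_type_size[as.character(type)]
  if (is.na(size)) return(list(tag = tag, values = NULL))
  size <- unname(size)
  nbytes <- size * count
  voff <- if (nbytes <= 4L) entry_off + 8L else .rd_int(raw, entry_off + 8L, 4L, endian)
  vals <- numeric(count)
  for (i in seq_len(count)) {
    o <- voff + (i - 1L) * size
    vals[i] <- switch(as.character(type),
      `1` = .rd_int(raw, o, 1L, endian),
      `3` = .rd_int(raw, o, 2L, endian),
      `4` = .rd_int(raw, o, 4L, endian),
      `11` = readBin(raw[(o + 1):(o + 4)], "double", 1L, size = 4L, endian = endian),
      `12` = readBin(raw[(o + 1):(o + 8)], "double", 1L, size = 8L, endian = endian),
      NA_real_)
  }
  list(tag = tag, values = vals)
}

.read_samples <- function(raw, off, n, bits, fmt, endian) {
  bytes <- raw[(off + 1):(off + n * bits / 8L)]
  if (fmt == 3L) {
    readBin(bytes, "double", n = n, size = bits / 8L, endian = endian)
  } else {
    if (bits == 32L) {
      v <- readBin(bytes, "integer", n = n, size = 4L, endian = endian)
      v <- as.numeric(v); v[v < 0] <- v[v < 0] + 2^32
      v
    } else {
      as.numeric(readBin(bytes, "integer", n = n, size = bits / 8L,
                         endian = endian, signed = FALSE))
    }
  }
}

#' Read a multi-page TIFF stack
#'
#' Supports uncompressed grayscale baseline TIFF (uint8/16/32, float32/64),
#' either endianness, multiple strips per page, and 1 or 2 samples per
#' pixel.  A 2-sample file is split into two channels on load.
#'
#' @param path Path to a TIFF file.
#' @return For 1 sample/pixel, a numeric `(frame, row, col)` array.  For 2
#'   samples/pixel, a list of two such arrays named `sample1`, `sample2`.
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  if (.rd_int(raw, 2L, 2L, endian) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- .rd_int(raw, 4L, 4L, endian)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- .rd_int(raw, ifd_off, 2L, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- .rd_entry_values(raw, ifd_off + 2L + (i - 1L) * 12L, endian)
      if (!is.null(e$values)) tags[[as.character(e$tag)]] <- e$values
    }
    width <- tags[["256"]]; height <- tags[["257"]]
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]][1]
    if (comp != 1L) stop("only uncompressed TIFF is supported (compression tag ",
                         comp, ")")
    spp <- if (is.null(tags[["277"]])) 1L else as.integer(tags[["277"]][1])
    bits <- if (is.null(tags[["258"]])) 1L else as.integer(tags[["258"]][1])
    fmt <- if (is.null(tags[["339"]])) 1L else as.integer(tags[["339"]][1])
    offsets <- tags[["273"]]; counts <- tags[["279"]]
    if (is.null(offsets)) stop("TIFF page missing strip offsets")
    rps <- if (is.null(tags[["278"]])) height else tags[["278"]][1]
    vals <- numeric(0)
    for (s in seq_along(offsets)) {
      rows_here <- min(rps, height - (s - 1L) * rps)
      n_here <- rows_here * width * spp
      vals <- c(vals, .read_samples(raw, offsets[s], n_here, bits, fmt, endian))
    }
    pages[[length(pages) + 1L]] <- list(width = as.integer(width),
                                        height = as.integer(height),
                                        spp = spp, vals = vals)
    ifd_off <- .rd_int(raw, ifd_off + 2L + n_entries * 12L, 4L, endian)
  }
  if (!length(pages)) stop("TIFF file contains no pages: ", path)
  w <- pages[[1]]$width; h <- pages[[1]]$height; spp <- pages[[1]]$spp
  for (p in pages)
    if (p$width != w || p$height != h || p$spp != spp)
      stop("TIFF pages have inconsistent shapes")
  nf <- length(pages)
  if (spp == 1L) {
    arr <- array(0, dim = c(nf, h, w))
    for (f in seq_len(nf))
      arr[f, , ] <- matrix(pages[[f]]$vals, h, w, byrow = TRUE)
    arr
  } else if (spp == 2L) {
    a1 <- array(0, dim = c(nf, h, w)); a2 <- a1
    for (f in seq_len(nf)) {
      v <- pages[[f]]$vals
      a1[f, , ] <- matrix(v[seq(1L, length(v), 2L)], h, w, byrow = TRUE)
      a2[f, , ] <- matrix(v[seq(2L, length(v), 2L)], h, w, byrow = TRUE)
    }
    list(sample1 = a1, sample2 = a2)
  } else stop("unsupported samples per pixel: ", spp)
}

.wr_entry <- function(con, tag, type, count, value, inline_size) {
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(as.integer(type), con, size = 2L, endian = "little")
  writeBin(as.integer(count), con, size = 4L, endian = "little")
  if (inline_size == 2L) {
    writeBin(as.integer(value), con, size = 2L, endian = "little")
    writeBin(0L, con, size = 2L, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
}

#' Write a stack as a multi-page TIFF
#'
#' Integer-valued data are stored as uint16 (or uint32 when values exceed
#' 65535); anything else as float64.  One strip per page, little-endian.
#'
#' @param data A numeric `(frame, row, col)` array or an `image_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(data, path) {
  if (inherits(data, "image_stack")) data <- data$data
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L, all(is.finite(data)))
  d <- dim(data); nf <- d[1]; h <- d[2]; w <- d[3]
  is_int <- all(data == round(data)) && all(data >= 0)
  if (is_int && max(data) <= 65535) { bits <- 16L; fmt <- 1L }
  else if (is_int && max(data) < 2^31) { bits <- 32L; fmt <- 1L }
  else { bits <- 64L; fmt <- 3L }
  page_bytes <- as.integer(h * w * bits / 8L)
  ifd_len <- 2L + 10L * 12L + 4L
  data_base <- 8L
  ifd_base <- as.integer(data_base + nf * page_bytes)
  if (is.na(ifd_base)) stop("stack too large for this TIFF writer (> 2 GB)")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_base, con, size = 4L, endian = "little")
  for (f in seq_len(nf)) {
    vals <- as.vector(t(matrix(data[f, , ], h, w)))  # row-major
    if (fmt == 1L) {
      if (bits == 16L) {
        writeBin(as.integer(vals), con, size = 2L, endian = "little")
      } else {
        iv <- as.integer(vals)
        writeBin(iv, con, size = 4L, endian = "little")
      }
    } else {
      writeBin(as.numeric(vals), con, size = 8L, endian = "little")
    }
  }
  for (f in seq_len(nf)) {
    writeBin(10L, con, size = 2L, endian = "little")
    strip_off <- as.integer(data_base + (f - 1L) * page_bytes)
    .wr_entry(con, 256L, 4L, 1L, w, 4L)            # ImageWidth
    .wr_entry(con, 257L, 4L, 1L, h, 4L)            # ImageLength
    .wr_entry(con, 258L, 3L, 1L, bits, 2L)         # BitsPerSample
    .wr_entry(con, 259L, 3L, 1L, 1L, 2L)           # Compression = none
    .wr_entry(con, 262L, 3L, 1L, 1L, 2L)           # Photometric = BlackIsZero
    .wr_entry(con, 273L, 4L, 1L, strip_off, 4L)    # StripOffsets
    .wr_entry(con, 277L, 3L, 1L, 1L, 2L)           # SamplesPerPixel
    .wr_entry(con, 278L, 4L, 1L, h, 4L)            # RowsPerStrip
    .wr_entry(con, 279L, 4L, 1L, page_bytes, 4L)   # StripByteCounts
    .wr_entry(con, 339L, 3L, 1L, fmt, 2L)          # SampleFormat
    next_off <- as.integer(if (f < nf) ifd_base + f * ifd_len else 0L)
    writeBin(next_off, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Load a dual-channel stack pair from TIFF files
#'
#' @param green_path Path to the green-channel TIFF.  If `red_path` is
#'   `NULL`, this file must hold 2 samples per pixel (green first) and is
#'   split on load.
#' @param red_path Path to the red-channel TIFF, or `NULL`.
#' @param frame_interval Time between frames in seconds.
#' @return `list(green =, red =)` of validated `image_stack`s.
#' @export
load_stack_pair <- function(green_path, red_path = NULL, frame_interval = 1) {
  if (!file.exists(green_path)) stop("missing input file: ", green_path)
  g <- read_tiff_stack(green_path)
  if (is.null(red_path)) {
    if (!is.list(g))
      stop("single-file load requires a 2-sample-per-pixel TIFF: ", green_path)
    green <- image_stack(g$sample1, "green", frame_interval)
    red <- image_stack(g$sample2, "red", frame_interval)
  } else {
    if (!file.exists(red_path)) stop("missing input file: ", red_path)
    r <- read_tiff_stack(red_path)
    if (is.list(g) || is.list(r))
      stop("per-channel files must hold 1 sample per pixel")
    green <- image_stack(g, "green", frame_interval)
    red <- image_stack(r, "red", frame_interval)
  }
  validate_stack_pair(green, red)
  list(green = green, red = red)
}
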