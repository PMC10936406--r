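#' Ordered 3D grayscale image stack
#'
#' The central container of the package: an ordered stack of grayscale SEM
#' slices with an isotropic in-plane pixel size.  Data are stored as a 3D
#' double array indexed `[slice z, row y, column x]`; slice order equals
#' acquisition (milling) order.  The coordinate convention everywhere in the
#' package is x = column index (SEM fast-scan direction), y = row index
#' (slow-scan), origin at the top-left pixel, 0-based in transform
#' coordinates.
#'
#' @param data numeric 3D array `[z, y, x]`, or a matrix (taken as a single
#'   slice).  All values must be finite.
#' @param pixel_size_nm positive in-plane pixel size in nanometres, or `NA`
#'   when unknown.
#' @return an object of class `image_stack` with fields `data`,
#'   `pixel_size_nm`, `n_slices`, `height`, `width`.
#' @export
image_stack <- function(data, pixel_size_nm = NA_real_) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array [slice, row, column] or a matrix")
  }
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("stack contains non-finite values")
  if (!is.na(pixel_size_nm)) {
    stopifnot_scalar_num(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  }
  structure(
    list(
      data = data,
      pixel_size_nm = as.numeric(pixel_size_nm),
      n_slices = dim(data)[1L],
      height = dim(data)[2L],
      width = dim(data)[3L]
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf(
    "<image_stack> %d slice(s), %d x %d px, pixel size %s nm\n",
    x$n_slices, x$height, x$width,
    if (is.na(x$pixel_size_nm)) "unknown" else format(x$pixel_size_nm)
  ))
  invisible(x)
}

#' Extract one slice of a stack as a `[row, column]` matrix
#' @param stack an [image_stack].
#' @param k slice index (1-based).
#' @return numeric matrix.
#' @export
get_slice <- function(stack, k) {
  stopifnot(inherits(stack, "image_stack"), k >= 1L, k <= stack$n_slices)
  matrix(stack$data[k, , ], nrow = stack$height, ncol = stack$width)
}

# ---------------------------------------------------------------------------
# TIFF helpers

# Reads all pages of a TIFF as a list of numeric matrices at their native
# values: float pages are used as-is, integer pages are scaled back from
# tiff's [0, 1] convention to raw integer counts (cast, not rescaled).
tiff_read_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] == 1L) p <- p[, , 1L] else stop("multi-channel TIFF not supported (grayscale only)")
    }
    fmt <- attr(p, "sample.format") %||% "uint"
    bits <- attr(p, "bits.per.sample") %||% 8L
    m <- matrix(as.numeric(p), nrow = nrow(p), ncol = ncol(p))
    if (!identical(fmt, "float")) m <- round(m * (2^bits - 1))
    attr(m, "x.resolution") <- attr(p, "x.resolution")
    attr(m, "resolution.unit") <- attr(p, "resolution.unit")
    m
  })
}

tiff_pixel_size_nm <- function(page) {
  xres <- attr(page, "x.resolution")
  unit <- attr(page, "resolution.unit") %||% "none"
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NA_real_)
  switch(unit,
    cm = 1e7 / xres,
    inch = 2.54e7 / xres,
    NA_real_
  )
}

# Minimal multipage grayscale float32 TIFF writer (little-endian, classic
# TIFF, uncompressed, one strip per page, SampleFormat = IEEE float).  Used
# for lossless float storage; values are written bit-for-bit, including
# values outside [0, 1].  Pixel size, when known, is stored as X/YResolution
# in pixels per centimetre.
write_tiff_float32 <- function(slices, path, pixel_size_nm = NA_real_) {
  con <- file(path, "wb")
  on.exit(close(con))
  wr_int <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  has_res <- is.finite(pixel_size_nm) && pixel_size_nm > 0
  n_tags <- if (has_res) 13L else 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  rat_size <- if (has_res) 16L else 0L

  writeChar("II", con, nchars = 2, eos = NULL)
  wr_int(42L, 2)
  wr_int(8L, 4) # first IFD directly after header

  pos <- 8L
  n <- length(slices)
  for (i in seq_len(n)) {
    m <- slices[[i]]
    h <- nrow(m); w <- ncol(m)
    data_size <- 4L * h * w
    rat_off <- pos + ifd_size
    data_off <- rat_off + rat_size
    next_ifd <- if (i < n) data_off + data_size else 0L

    tag <- function(id, type, count, value) {
      wr_int(id, 2); wr_int(type, 2); wr_int(count, 4)
      if (type == 3L && count == 1L) { # SHORT packed left-justified
        wr_int(value, 2); wr_int(0L, 2)
      } else {
        wr_int(value, 4)
      }
    }
    wr_int(n_tags, 2)
    tag(256L, 4L, 1L, w)          # ImageWidth
    tag(257L, 4L, 1L, h)          # ImageLength
    tag(258L, 3L, 1L, 32L)        # BitsPerSample
    tag(259L, 3L, 1L, 1L)         # Compression = none
    tag(262L, 3L, 1L, 1L)         # Photometric = BlackIsZero
    tag(273L, 4L, 1L, data_off)   # StripOffsets
    tag(277L, 3L, 1L, 1L)         # SamplesPerPixel
    tag(278L, 4L, 1L, h)          # RowsPerStrip
    tag(279L, 4L, 1L, data_size)  # StripByteCounts
    if (has_res) {
      tag(282L, 5L, 1L, rat_off)        # XResolution (RATIONAL)
      tag(283L, 5L, 1L, rat_off + 8L)   # YResolution
      tag(296L, 3L, 1L, 3L)             # ResolutionUnit = cm
    }
    tag(339L, 3L, 1L, 3L)         # SampleFormat = IEEE float
    wr_int(next_ifd, 4)

    if (has_res) {
      # pixels per cm = 1e9 / (100 * pixel_size_nm), to 0.01 nm precision
      den <- max(1L, as.integer(round(100 * pixel_size_nm)))
      wr_int(1e9, 4); wr_int(den, 4)
      wr_int(1e9, 4); wr_int(den, 4)
    }
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    pos <- data_off + data_size
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# MRC2014 (minimal): modes 0 (int8), 1 (int16), 2 (float32), 6 (uint16).

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_int <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rd_flt <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  nxyz <- rd_int(3)
  mode <- rd_int(1)
  rd_int(3) # nxstart..nzstart
  mxyz <- rd_int(3)
  cella <- rd_flt(3)
  invisible(rd_flt(3)) # cellb
  invisible(rd_int(3)) # mapc/mapr/maps
  invisible(rd_flt(3)) # dmin/dmax/dmean
  invisible(rd_int(1)) # ispg
  nsymbt <- rd_int(1)
  seek(con, 1024 + nsymbt)
  nvox <- prod(nxyz)
  vec <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2, signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = nvox, size = 2, signed = FALSE, endian = "little")),
    stop(sprintf("unsupported MRC mode %d", mode))
  )
  if (length(vec) != nvox) stop("truncated MRC data block")
  a <- array(vec, dim = nxyz)          # x fastest, then y, then z
  data <- aperm(a, c(3L, 2L, 1L))      # -> [z, y, x]
  px <- if (cella[1] > 0 && mxyz[1] > 0) cella[1] / mxyz[1] / 10 else NA_real_
  list(data = data, pixel_size_nm = px)
}

write_mrc <- function(data, path, pixel_size_nm = NA_real_, mode = 2L) {
  con <- file(path, "wb")
  on.exit(close(con))
  wr_int <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wr_flt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  d <- dim(data)
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  px_a <- if (is.finite(pixel_size_nm)) pixel_size_nm * 10 else 0
  vec <- as.vector(aperm(data, c(3L, 2L, 1L)))
  wr_int(c(nx, ny, nz))
  wr_int(mode)
  wr_int(c(0L, 0L, 0L))
  wr_int(c(nx, ny, nz))
  wr_flt(c(nx, ny, nz) * px_a)
  wr_flt(c(90, 90, 90))
  wr_int(c(1L, 2L, 3L))
  wr_flt(c(min(vec), max(vec), mean(vec)))
  wr_int(c(0L, 0L))                 # ispg, nsymbt
  wr_int(rep(0L, 25))               # extra (incl. exttyp); nversion left 0
  wr_flt(c(0, 0, 0))                # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wr_flt(sd(vec))
  wr_int(1L)                        # nlabl
  lab <- sprintf("%-80s", "fibsemtools")
  writeChar(substr(lab, 1, 80), con, nchars = 80, eos = NULL)
  writeBin(raw(800 - 80), con)
  if (mode == 2L) {
    wr_flt(vec)
  } else if (mode == 6L) {
    writeBin(as.integer(round(vec)), con, size = 2, endian = "little")
  } else {
    stop("write_mrc supports modes 2 and 6 only")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Read a 3D image stack from a multipage TIFF or MRC file
#'
#' Intensities are cast to double without rescaling (integer TIFF samples
#' keep their raw counts).  The in-plane pixel size is taken from the
#' explicit argument first, then from file metadata (TIFF resolution tags in
#' cm/inch units, or the MRC cell dimensions); if neither is available the
#' stack is loaded with pixel size `NA` unless `require_pixel_size = TRUE`.
#'
#' @param path file path; format chosen by extension (`.tif`/`.tiff` or
#'   `.mrc`/`.rec`).
#' @param pixel_size_nm optional explicit pixel size in nm; takes precedence
#'   over file metadata.
#' @param require_pixel_size error if no pixel size can be determined.
#' @return an [image_stack]; page/section `k` of the file is slice `k`.
#' @export
read_stack <- function(path, pixel_size_nm = NULL, require_pixel_size = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff_read_pages(path)
    dims <- unique(lapply(pages, dim))
    if (length(dims) != 1L) stop("inconsistent slice shapes across TIFF pages")
    h <- dims[[1L]][1L]; w <- dims[[1L]][2L]
    data <- array(0, dim = c(length(pages), h, w))
    for (k in seq_along(pages)) data[k, , ] <- pages[[k]]
    meta_px <- tiff_pixel_size_nm(pages[[1L]])
  } else if (ext %in% c("mrc", "rec")) {
    m <- read_mrc(path)
    data <- m$data
    meta_px <- m$pixel_size_nm
  } else {
    stop(sprintf("unsupported stack format: .%s (use TIFF or MRC)", ext))
  }
  px <- if (!is.null(pixel_size_nm)) pixel_size_nm else meta_px
  if ((is.null(px) || is.na(px)) && require_pixel_size) {
    stop("pixel size is neither given nor present in file metadata")
  }
  image_stack(data, pixel_size_nm = if (is.null(px)) NA_real_ else px)
}

#' Write a 3D image stack to a multipage TIFF or MRC file
#'
#' @param stack an [image_stack] or a numeric 3D `[z, y, x]` array / matrix.
#' @param path output path; format chosen by extension.
#' @param dtype_policy `"preserve-float32"` writes IEEE float samples
#'   bit-for-bit; `"rescale-uint8"` / `"rescale-uint16"` min-max rescale the
#'   stack to the full unsigned integer range (a constant stack maps to 0).
#'   Non-finite values under an integer policy raise an error rather than
#'   being clipped.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path,
                        dtype_policy = c("preserve-float32", "rescale-uint8",
                                         "rescale-uint16")) {
  dtype_policy <- match.arg(dtype_policy)
  if (inherits(stack, "image_stack")) {
    data <- stack$data
    px <- stack$pixel_size_nm
  } else {
    if (is.matrix(stack)) stack <- array(stack, dim = c(1L, nrow(stack), ncol(stack)))
    data <- stack
    px <- NA_real_
  }
  if (!dir.exists(dirname(path))) stop(sprintf("directory does not exist: %s", dirname(path)))
  integer_policy <- dtype_policy != "preserve-float32"
  if (integer_policy && !all(is.finite(data))) {
    stop("non-finite values cannot be written under an integer dtype policy")
  }
  rescale01 <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(array(0, dim = dim(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  ext <- tolower(tools::file_ext(path))
  nz <- dim(data)[1L]
  slices <- lapply(seq_len(nz), function(k) matrix(data[k, , ], dim(data)[2L], dim(data)[3L]))
  if (ext %in% c("tif", "tiff")) {
    if (dtype_policy == "preserve-float32") {
      write_tiff_float32(slices, path, pixel_size_nm = px)
    } else {
      bits <- if (dtype_policy == "rescale-uint8") 8L else 16L
      scaled <- rescale01(data)
      pages <- lapply(seq_len(nz), function(k) matrix(scaled[k, , ], dim(data)[2L], dim(data)[3L]))
      tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
    }
  } else if (ext %in% c("mrc", "rec")) {
    if (dtype_policy == "preserve-float32") {
      write_mrc(data, path, pixel_size_nm = px, mode = 2L)
    } else {
      top <- if (dtype_policy == "rescale-uint8") 255 else 65535
      write_mrc(round(rescale01(data) * top), path, pixel_size_nm = px, mode = 6L)
    }
  } else {
    stop(sprintf("unsupported stack format: .%s (use TIFF or MRC)", ext))
  }
  invisible(path)
}

#' Read a charging-centre label mask
#'
#' Masks are nonnegative integer images (0 = background, >0 = label) in PNG
#' or TIFF form, either a single 2D mask or a multipage mask matching a full
#' stack.  Floating-point files are accepted only when every value is
#' integral.
#'
#' @param path PNG or TIFF file.
#' @param expected_shape optional `c(height, width)` (or
#'   `c(slices, height, width)`) that the mask must match.
#' @return integer matrix (or 3D array) of class `label_mask`.
#' @export
read_mask <- function(path, expected_shape = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) {
      if (dim(v)[3L] == 1L) v <- v[, , 1L] else stop("multi-channel PNG masks not supported")
    }
    # png scales to [0,1]; recover 8-bit counts first, else 16-bit counts
    pages <- NULL
    for (s in c(255, 65535)) {
      m <- v * s
      if (max(abs(m - round(m))) < 1e-6) { pages <- list(round(m)); break }
    }
    if (is.null(pages)) stop("PNG mask has non-integral values")
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff_read_pages(path)
    bad <- vapply(pages, function(p) max(abs(p - round(p))) >= 1e-6, logical(1))
    if (any(bad)) stop("floating-point mask has non-integral values")
    pages <- lapply(pages, round)
  } else {
    stop(sprintf("unsupported mask format: .%s (use PNG or TIFF)", ext))
  }
  if (any(vapply(pages, function(p) any(p < 0), logical(1)))) {
    stop("mask contains negative values")
  }
  out <- if (length(pages) == 1L) {
    m <- pages[[1L]]
    storage.mode(m) <- "integer"
    m
  } else {
    a <- array(0L, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
    for (k in seq_along(pages)) a[k, , ] <- as.integer(pages[[k]])
    a
  }
  if (!is.null(expected_shape)) {
    got <- dim(out)
    if (length(got) != length(expected_shape) || !all(got == expected_shape)) {
      stop(sprintf(
        "mask shape (%s) does not match expected shape (%s)",
        paste(got, collapse = "x"), paste(expected_shape, collapse = "x")
      ))
    }
  }
  class(out) <- c("label_mask", class(out))
  out
}
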