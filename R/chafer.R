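#' Shifted logistic sigmoid model for one charging-artifact tail
#'
#' Charging tails extend along the fast-scan x direction on either side of a
#' labelled charging centre and look like smoothed steps: saturated next to
#' the centre, decaying to zero away from it.  Each tail is modelled by a
#' three-parameter shifted logistic (Fermi-Dirac type) curve
#' `f(x) = amplitude / (1 + exp(s (x - center) / width))` with `s = -1` for
#' the left tail and `s = +1` for the right tail, so the curve saturates
#' toward `amplitude` approaching the labelled segment and tends to 0 away
#' from it.
#'
#' @param side `"left"` or `"right"` of the labelled segment.
#' @param amplitude signed saturation level (intensity units; negative for
#'   dark tails).
#' @param center column coordinate of the half-amplitude point (pixels).
#' @param width positive decay width (pixels).
#' @return a `sigmoid_tail_model` object.
#' @export
sigmoid_tail_model <- function(side = c("left", "right"), amplitude, center, width) {
  side <- match.arg(side)
  stopifnot_scalar_num(amplitude, "amplitude")
  stopifnot_scalar_num(center, "center")
  stopifnot_scalar_num(width, "width", positive = TRUE)
  structure(list(side = side, amplitude = amplitude, center = center,
                 width = width),
            class = "sigmoid_tail_model")
}

#' Evaluate a sigmoid tail model
#'
#' @param x column coordinate(s), pixels.
#' @param model a [sigmoid_tail_model].
#' @return numeric vector of tail values; the exponent is clamped to avoid
#'   overflow.
#' @export
sigmoid_tail <- function(x, model) {
  s <- if (model$side == "left") -1 else 1
  z <- s * (x - model$center) / model$width
  z <- pmin(pmax(z, -700), 700)
  model$amplitude / (1 + exp(z))
}

#' Chafer filter parameters
#'
#' @param n_lines_average number of preceding rows averaged for the
#'   row-background estimate (>= 1).
#' @param passes `"down"`, `"up"` or `"both"`; with `"both"` the output is
#'   the mean of the two pass results.
#' @param fit_max_iter,fit_tolerance Levenberg-Marquardt controls for the
#'   tail fits.
#' @param clip_output clamp the output to the input intensity range.
#' @return a `chafer_params` object.
#' @export
chafer_params <- function(n_lines_average = 5L, passes = c("both", "down", "up"),
                          fit_max_iter = 100L, fit_tolerance = 1e-8,
                          clip_output = FALSE) {
  passes <- match.arg(passes)
  n_lines_average <- as.integer(n_lines_average)
  if (n_lines_average < 1L) stop("`n_lines_average` must be >= 1")
  structure(list(n_lines_average = n_lines_average, passes = passes,
                 fit_max_iter = as.integer(fit_max_iter),
                 fit_tolerance = fit_tolerance,
                 clip_output = isTRUE(clip_output)),
            class = "chafer_params")
}

#' Labelled intervals of a mask row
#'
#' Maximal runs of nonzero mask pixels in one row, as inclusive 0-based
#' column intervals sorted by start.
#'
#' @param mask integer label mask (matrix).
#' @param row row index, 1-based.
#' @return data.frame with columns `x_start`, `x_end` (0-based, inclusive);
#'   zero rows when the row is unlabelled.
#' @export
extract_row_segments <- function(mask, row) {
  stopifnot(row >= 1L, row <= nrow(mask))
  v <- mask[row, ] != 0
  if (!any(v)) {
    return(data.frame(x_start = integer(0), x_end = integer(0)))
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  data.frame(x_start = starts[on] - 1L, x_end = ends[on] - 1L)
}

#' Row background estimate from preceding rows
#'
#' Per-column mean over the up-to-`n_lines_average` rows preceding `row` in
#' the pass direction (above for a down pass, below for an up pass),
#' excluding masked pixels column-wise.  The preceding rows are taken from
#' `working_image`, i.e. the already-corrected rows of the running pass.
#' Columns masked in all contributing rows fall back to the mean of the
#' row's valid background values.
#'
#' @param working_image numeric matrix (the progressively corrected image).
#' @param mask integer label mask of the same shape.
#' @param row row index, 1-based.
#' @param n_lines_average rows to average.
#' @param direction `"down"` (predecessors above) or `"up"` (below).
#' @return numeric background profile of length `ncol(working_image)`.
#' @export
estimate_row_background <- function(working_image, mask, row, n_lines_average,
                                    direction = c("down", "up")) {
  direction <- match.arg(direction)
  ny <- nrow(working_image)
  rows <- if (direction == "down") {
    seq(max(1L, row - n_lines_average), row - 1L)
  } else {
    seq(row + 1L, min(ny, row + n_lines_average))
  }
  if (row == 1L && direction == "down" || row == ny && direction == "up") {
    stop("row has no preceding rows in the pass direction")
  }
  block <- working_image[rows, , drop = FALSE]
  valid <- mask[rows, , drop = FALSE] == 0
  cnt <- colSums(valid)
  tot <- colSums(block * valid)
  prof <- ifelse(cnt > 0, tot / pmax(cnt, 1L), NA_real_)
  if (anyNA(prof)) {
    fallback <- mean(prof, na.rm = TRUE)
    if (is.nan(fallback)) fallback <- mean(block)
    prof[is.na(prof)] <- fallback
  }
  prof
}

#' Fit left and right sigmoid tails around one labelled segment
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [sigmoid_tail()] against
#' the background-subtracted row signal over the windows to the left and
#' right of the segment.  Windows are bounded by the neighbouring segments
#' (or the row ends) and exclude invalid (masked) columns.  Initial values
#' come from the segment geometry: amplitude from the mean signal over the 5
#' valid pixels adjacent to the boundary, centre at the boundary, width
#' `max(2, segment length / 4)`.  A side whose window has fewer than 4 valid
#' pixels, or whose fit fails to converge, returns `NULL`.
#'
#' @param diff_signal numeric vector: current row minus background; masked
#'   columns should be `NA`.
#' @param segments segment table from [extract_row_segments()].
#' @param segment_index which segment to fit around (1-based).
#' @param control optional list with `maxiter` and `ftol`.
#' @return `list(left = , right = )` of [sigmoid_tail_model] or `NULL`.
#' @export
fit_tail_sigmoids <- function(diff_signal, segments, segment_index,
                              control = list()) {
  stopifnot(segment_index >= 1L, segment_index <= nrow(segments))
  nx <- length(diff_signal)
  seg <- segments[segment_index, ]
  lo_bound <- if (segment_index > 1L) segments$x_end[segment_index - 1L] + 1L else 0L
  hi_bound <- if (segment_index < nrow(segments)) {
    segments$x_start[segment_index + 1L] - 1L
  } else {
    nx - 1L
  }
  seg_len <- seg$x_end - seg$x_start + 1L
  fit_side <- function(side, from, to, center0) {
    if (to < from) return(NULL)
    xs <- from:to
    ys <- diff_signal[xs + 1L]
    ok <- is.finite(ys)
    if (sum(ok) < 4L) return(NULL)
    xs <- xs[ok]; ys <- ys[ok]
    if (all(abs(ys) < 1e-8)) {
      # flat zero difference: the exact solution is a zero-amplitude tail
      return(sigmoid_tail_model(side, amplitude = 0, center = center0,
                                width = max(2, seg_len / 4)))
    }
    near <- if (side == "left") utils::tail(order(xs), 5L) else utils::head(order(xs), 5L)
    a0 <- mean(ys[near])
    if (!is.finite(a0)) return(NULL)
    w0 <- max(2, seg_len / 4)
    sgn <- if (side == "left") -1 else 1
    df <- data.frame(x = xs, y = ys)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ a / (1 + exp(pmin(pmax(sgn * (x - b) / c, -700), 700))),
        data = df,
        start = list(a = a0, b = center0, c = w0),
        lower = c(-Inf, -Inf, 1e-3),
        control = minpack.lm::nls.lm.control(
          maxiter = control$maxiter %||% 100L,
          ftol = control$ftol %||% 1e-10
        )
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    p <- coef(fit)
    if (!all(is.finite(p)) || p[["c"]] <= 0) return(NULL)
    sigmoid_tail_model(side, amplitude = p[["a"]], center = p[["b"]],
                       width = p[["c"]])
  }
  list(
    left = fit_side("left", lo_bound, seg$x_start - 1L, seg$x_start),
    right = fit_side("right", seg$x_end + 1L, hi_bound, seg$x_end)
  )
}

#' Subtract fitted tail models from one row
#'
#' Each fitted sigmoid is subtracted over its window (left: from the
#' previous segment / row start to just before the segment; right:
#' symmetric) from unmasked pixels only; masked pixels are returned
#' unchanged so the charging object itself is preserved.
#'
#' @param row_values numeric row.
#' @param segments segment table from [extract_row_segments()].
#' @param fits list, one element per segment, each as returned by
#'   [fit_tail_sigmoids()].
#' @param mask_row logical or integer vector marking masked pixels.
#' @return corrected numeric row.
#' @export
correct_row <- function(row_values, segments, fits, mask_row = NULL) {
  nx <- length(row_values)
  if (is.null(mask_row)) mask_row <- rep(FALSE, nx)
  masked <- mask_row != 0
  out <- row_values
  if (nrow(segments) == 0L) return(out)
  stopifnot(length(fits) == nrow(segments))
  for (i in seq_len(nrow(segments))) {
    f <- fits[[i]]
    if (is.null(f)) next
    lo_bound <- if (i > 1L) segments$x_end[i - 1L] + 1L else 0L
    hi_bound <- if (i < nrow(segments)) segments$x_start[i + 1L] - 1L else nx - 1L
    if (!is.null(f$left) && segments$x_start[i] - 1L >= lo_bound) {
      xs <- lo_bound:(segments$x_start[i] - 1L)
      sel <- xs + 1L
      use <- !masked[sel]
      out[sel[use]] <- out[sel[use]] - sigmoid_tail(xs[use], f$left)
    }
    if (!is.null(f$right) && segments$x_end[i] + 1L <= hi_bound) {
      xs <- (segments$x_end[i] + 1L):hi_bound
      sel <- xs + 1L
      use <- !masked[sel]
      out[sel[use]] <- out[sel[use]] - sigmoid_tail(xs[use], f$right)
    }
  }
  out
}

# One sequential pass over the image.  Returns list(image, n_fits, n_failed).
chafer_pass <- function(image, mask, params, direction) {
  ny <- nrow(image)
  work <- image
  rows <- if (direction == "down") seq_len(ny) else rev(seq_len(ny))
  n_fits <- 0L
  n_failed <- 0L
  for (row in rows) {
    segs <- extract_row_segments(mask, row)
    if (nrow(segs) == 0L) next
    if ((direction == "down" && row == 1L) || (direction == "up" && row == ny)) {
      next # no predecessors in this pass; the other pass covers it
    }
    bg <- estimate_row_background(work, mask, row, params$n_lines_average,
                                  direction)
    diff <- work[row, ] - bg
    diff[mask[row, ] != 0] <- NA_real_
    fits <- lapply(seq_len(nrow(segs)), function(i) {
      fit_tail_sigmoids(diff, segs, i,
                        control = list(maxiter = params$fit_max_iter,
                                       ftol = params$fit_tolerance))
    })
    for (f in fits) {
      n_fits <- n_fits + sum(!vapply(f, is.null, logical(1)))
      n_failed <- n_failed + sum(vapply(f, is.null, logical(1)))
    }
    work[row, ] <- correct_row(work[row, ], segs, fits, mask_row = mask[row, ])
  }
  list(image = work, n_fits = n_fits, n_failed = n_failed)
}

#' Suppress charging-artifact tails around labelled centres
#'
#' Runs the row-by-row restoration: in each pass a row's clean background is
#' estimated from the already-corrected preceding rows (averaged
#' perpendicular to the scan direction, masked pixels excluded), the
#' difference signal is modelled by shifted logistic sigmoids on the left
#' and right of every labelled segment, and the fitted tails are subtracted
#' from the unmasked pixels.  A top-to-bottom and a bottom-to-top pass are
#' run and averaged (default).  Rows without labelled segments, and all
#' pixels under the mask, are never modified; an empty mask returns the
#' input bitwise.
#'
#' @param image numeric matrix.
#' @param mask integer label mask of the same shape.
#' @param params a [chafer_params].
#' @return corrected matrix with attribute `fit_log` (counts of fitted and
#'   failed tail fits per pass).
#' @export
chafer_filter <- function(image, mask, params = chafer_params()) {
  check_image(image)
  if (!all(dim(mask) == dim(image))) {
    stop(sprintf(
      "mask shape (%s) does not match image shape (%s)",
      paste(dim(mask), collapse = "x"), paste(dim(image), collapse = "x")
    ))
  }
  if (all(mask == 0)) {
    out <- image
    attr(out, "fit_log") <- list(down = NULL, up = NULL, note = "empty mask: no-op")
    return(out)
  }
  log <- list()
  if (params$passes %in% c("down", "both")) {
    pd <- chafer_pass(image, mask, params, "down")
    log$down <- pd[c("n_fits", "n_failed")]
  }
  if (params$passes %in% c("up", "both")) {
    pu <- chafer_pass(image, mask, params, "up")
    log$up <- pu[c("n_fits", "n_failed")]
  }
  out <- switch(params$passes,
    down = pd$image,
    up = pu$image,
    both = (pd$image + pu$image) / 2
  )
  if (params$clip_output) {
    rng <- range(image)
    out <- pmin(pmax(out, rng[1]), rng[2])
  }
  attr(out, "fit_log") <- log
  out
}

#' Background standard deviation near charging centres, before vs after
#'
#' Computes the standard deviation of intensities over unmasked pixels
#' within a Chebyshev distance `radius_px` of any labelled pixel, for the
#' uncorrected and corrected images, and the percent reduction
#' `100 (1 - sd_after / sd_before)`.
#'
#' @param before,after numeric matrices of equal shape.
#' @param mask integer label mask of the same shape with at least one
#'   labelled pixel.
#' @param radius_px neighbourhood radius in pixels (Chebyshev metric).
#' @return list with `std_before`, `std_after`, `percent_reduction`,
#'   `n_pixels`.
#' @export
background_std_report <- function(before, after, mask, radius_px = 50L) {
  check_image(before, "before"); check_image(after, "after")
  if (!all(dim(before) == dim(after)) || !all(dim(before) == dim(mask))) {
    stop("`before`, `after` and `mask` must share one shape")
  }
  if (all(mask == 0)) stop("mask has no labelled pixels")
  lab <- (mask != 0) * 1
  brush <- matrix(1, 2L * radius_px + 1L, 2L * radius_px + 1L)
  near <- EBImage::imageData(EBImage::dilate(lab, brush)) > 0
  region <- near & (mask == 0)
  if (!any(region)) stop("no unmasked pixels within the requested radius")
  s_before <- sd(before[region])
  s_after <- sd(after[region])
  list(
    std_before = s_before,
    std_after = s_after,
    percent_reduction = 100 * (1 - s_after / s_before),
    n_pixels = sum(region)
  )
}
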