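#' Fourier ring correlation between two images
#'
#' The two images are tapered, Fourier transformed, and the normalized
#' cross-spectral correlation is computed over concentric rings of spatial
#' frequency:
#' `corr(q) = Re{ sum F1 conj(F2) } / sqrt( sum |F1|^2 sum |F2|^2 )`,
#' summed over the DFT bins whose radius falls in ring `q`.  Frequencies
#' are normalized so the outermost computed ring equals 1 (a 2-pixel
#' period).
#'
#' @param img1,img2 equal square numeric matrices.
#' @param ring_width_bins ring width in radial DFT bins (default 1).
#' @param window `"hann"` (separable 2D Hann taper) or `"none"`.
#' @return an `frc_curve`: list with `freq` (strictly increasing, in
#'   `(0, 1]`), `corr`, and `n_bins` per ring.
#' @export
compute_frc <- function(img1, img2, ring_width_bins = 1L,
                        window = c("hann", "none")) {
  check_image(img1, "img1"); check_image(img2, "img2")
  window <- match.arg(window)
  if (!all(dim(img1) == dim(img2))) stop("images must have the same shape")
  if (nrow(img1) != ncol(img1)) stop("images must be square (pad or crop upstream)")
  if (all(img1 == 0) || all(img2 == 0)) {
    stop("all-zero image: FRC normalization undefined")
  }
  n <- nrow(img1)
  w <- if (window == "hann") outer(hann_window(n), hann_window(n)) else 1
  F1 <- fft(img1 * w)
  F2 <- fft(img2 * w)
  rings <- frc_ring_index(n, ring_width_bins)
  num <- rowsum_by(Re(F1 * Conj(F2)), rings$idx, rings$n_rings)
  p1 <- rowsum_by(Mod(F1)^2, rings$idx, rings$n_rings)
  p2 <- rowsum_by(Mod(F2)^2, rings$idx, rings$n_rings)
  denom <- sqrt(p1 * p2)
  corr <- ifelse(denom > 0, num / denom, 0)
  structure(
    list(freq = rings$freq, corr = corr, n_bins = rings$counts,
         n_px = n, window = window),
    class = "frc_curve"
  )
}

# Ring assignment for an n x n DFT: bin (u, v) with signed frequencies gets
# ring round(radius) (bins of width 1), grouped by `width`; DC and rings
# beyond n/2 are dropped (idx 0).
frc_ring_index <- function(n, width = 1L) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  if (n %% 2 == 0) f <- c(0:(n %/% 2 - 1), -(n %/% 2), -((n %/% 2 - 1):1))
  fx <- matrix(rep(f, each = n), n, n)
  fy <- matrix(rep(f, times = n), n, n)
  radius <- sqrt(fx^2 + fy^2)
  ring <- as.integer(round(radius))
  nyq <- n %/% 2
  ring[ring < 1L | ring > nyq] <- 0L
  grp <- as.integer(ceiling(ring / width))
  grp[ring == 0L] <- 0L
  n_rings <- as.integer(ceiling(nyq / width))
  counts <- tabulate(grp, nbins = n_rings)
  keep <- counts > 0L
  # ring centre frequency normalized by the Nyquist ring
  centres <- (seq_len(n_rings) * width - (width - 1) / 2) / nyq
  list(idx = grp, n_rings = n_rings, counts = counts[keep],
       freq = pmin(centres[keep], 1), keep = keep)
}

rowsum_by <- function(values, idx, n_rings) {
  s <- rowsum(as.vector(values), group = idx)
  lab <- as.integer(rownames(s))
  out <- numeric(n_rings)
  out[lab[lab > 0L]] <- s[lab > 0L, 1L]
  out[tabulate(idx, nbins = n_rings) > 0L]
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("<frc_curve> %d rings, corr[1] = %.3f, corr[last] = %.3f\n",
              length(x$freq), x$corr[1], x$corr[length(x$corr)]))
  invisible(x)
}

#' Resolution from an FRC curve by threshold crossing
#'
#' Finds the first ring where the correlation drops below `threshold` and
#' linearly interpolates the crossing frequency between the bracketing
#' rings.  Resolution in pixels is `2 / f_crossing` (so `f = 1`, the
#' outermost ring, corresponds to a 2-pixel period); multiplied by the
#' pixel size when given.  A curve that never drops below the threshold is
#' flagged `"at-limit"` with `f_crossing = 1`; one already below it at the
#' first ring is flagged `"unresolved"`.
#'
#' @param curve an `frc_curve`.
#' @param threshold correlation threshold (default 1/7, printed as 0.143).
#' @param pixel_size_nm optional pixel size for a physical resolution.
#' @return a `resolution_result`: `f_crossing`, `resolution_px`,
#'   `resolution_nm`, `threshold`, `status`, `calibrated`.
#' @export
resolution_from_curve <- function(curve, threshold = 1 / 7,
                                  pixel_size_nm = NULL) {
  stopifnot(inherits(curve, "frc_curve"))
  f <- curve$freq; c_ <- curve$corr
  if (length(f) == 0L) stop("empty FRC curve")
  below <- which(c_ < threshold)
  if (length(below) == 0L) {
    fc <- 1; status <- "at-limit"
  } else if (below[1L] == 1L) {
    fc <- f[1L]; status <- "unresolved"
  } else {
    j <- below[1L]
    fc <- f[j - 1L] + (c_[j - 1L] - threshold) / (c_[j - 1L] - c_[j]) *
      (f[j] - f[j - 1L])
    status <- "ok"
  }
  res_px <- 2 / fc
  structure(
    list(
      f_crossing = fc,
      resolution_px = res_px,
      resolution_nm = if (!is.null(pixel_size_nm)) res_px * pixel_size_nm else NA_real_,
      threshold = threshold,
      status = status,
      calibrated = FALSE
    ),
    class = "resolution_result"
  )
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf(
    "<resolution_result> f_crossing = %.4f, resolution = %.3f px%s [%s%s]\n",
    x$f_crossing, x$resolution_px,
    if (is.finite(x$resolution_nm)) sprintf(" = %.2f nm", x$resolution_nm) else "",
    x$status, if (x$calibrated) ", calibrated" else ""
  ))
  invisible(x)
}

#' Split an image into its four checkerboard parity sub-images
#'
#' Pixels are classed by (row parity, column parity); each class forms a
#' half-size sub-image and together the four partition the (evenly cropped)
#' image exactly.  Parity is counted from the first pixel (index 0 = even).
#'
#' @param image numeric matrix, at least 2x2; odd trailing row/column is
#'   cropped.
#' @return list `sub_ee`, `sub_oo`, `sub_eo`, `sub_oe` (row parity then
#'   column parity).
#' @export
checkerboard_split <- function(image) {
  check_image(image)
  ny <- nrow(image); nx <- ncol(image)
  if (ny < 2L || nx < 2L) stop("image smaller than 2x2")
  ny <- ny - ny %% 2L; nx <- nx - nx %% 2L
  img <- image[seq_len(ny), seq_len(nx)]
  er <- seq(1L, ny, by = 2L); or <- seq(2L, ny, by = 2L)
  ec <- seq(1L, nx, by = 2L); oc <- seq(2L, nx, by = 2L)
  list(
    sub_ee = img[er, ec, drop = FALSE],
    sub_oo = img[or, oc, drop = FALSE],
    sub_eo = img[er, oc, drop = FALSE],
    sub_oe = img[or, ec, drop = FALSE]
  )
}

#' One-image FRC resolution by checkerboard subsampling
#'
#' Splits the image into its four checkerboard sub-images, computes the FRC
#' between the two diagonal pairs (even-even vs odd-odd, even-odd vs
#' odd-even), averages the two curves and extracts the threshold-crossing
#' resolution.  The sub-images are treated as contiguous grids at the
#' original pixel pitch; the geometric bias this introduces (the one-image
#' curve is shifted relative to the two-image gold standard, reporting
#' finer values) is exactly what an instrument calibration absorbs.
#'
#' @param image numeric matrix, at least 32x32.
#' @param calibration optional [calibration_model] mapping the uncalibrated
#'   one-image resolution to the two-image scale.
#' @param threshold FRC threshold.
#' @param pixel_size_nm optional pixel size (nm).
#' @param window taper passed to [compute_frc()].
#' @return a `resolution_result`; `calibrated` records whether the
#'   calibration was applied, and `resolution_px_uncalibrated` keeps the
#'   raw value.
#' @export
one_image_frc <- function(image, calibration = NULL, threshold = 1 / 7,
                          pixel_size_nm = NULL, window = "hann") {
  check_image(image)
  if (nrow(image) < 32L || ncol(image) < 32L) stop("image must be at least 32x32")
  sub <- checkerboard_split(image)
  c1 <- compute_frc(sub$sub_ee, sub$sub_oo, window = window)
  c2 <- compute_frc(sub$sub_eo, sub$sub_oe, window = window)
  avg <- c1
  avg$corr <- (c1$corr + c2$corr) / 2
  res <- resolution_from_curve(avg, threshold = threshold,
                               pixel_size_nm = pixel_size_nm)
  res$resolution_px_uncalibrated <- res$resolution_px
  if (!is.null(calibration)) {
    mapped <- predict_calibration(calibration, res$resolution_px)
    res$resolution_px <- mapped$value
    res$outside_domain <- mapped$outside_domain
    if (!is.null(pixel_size_nm)) res$resolution_nm <- mapped$value * pixel_size_nm
    res$calibrated <- TRUE
  }
  res$curve <- avg
  res
}

#' Power-law calibration between one-image and two-image FRC resolutions
#'
#' @param alpha,beta coefficients of `d_2img = alpha * d_1img^beta`.
#' @param domain fitted range `c(d_min, d_max)` of one-image resolutions.
#' @param provenance free-form list (pixel sizes, number of pairs).
#' @return a `calibration_model`.
#' @export
calibration_model <- function(alpha, beta, domain = c(-Inf, Inf),
                              provenance = list()) {
  stopifnot_scalar_num(alpha, "alpha", positive = TRUE)
  stopifnot_scalar_num(beta, "beta")
  structure(
    list(family = "power_law", alpha = alpha, beta = beta,
         domain = as.numeric(domain), provenance = provenance,
         monotone = beta > 0),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> d_2img = %.4g * d_1img^%.4g, domain [%.3g, %.3g]\n",
    x$alpha, x$beta, x$domain[1], x$domain[2]
  ))
  invisible(x)
}

#' Identity calibration (maps a resolution to itself)
#' @return a [calibration_model] with `alpha = 1`, `beta = 1`.
#' @export
identity_calibration <- function() calibration_model(1, 1)

#' Apply a calibration model to an uncalibrated resolution
#' @param model a [calibration_model].
#' @param d_1img uncalibrated one-image resolution(s), pixels.
#' @return list with `value` and `outside_domain` flag.
#' @export
predict_calibration <- function(model, d_1img) {
  stopifnot(inherits(model, "calibration_model"))
  outside <- d_1img < model$domain[1] | d_1img > model$domain[2]
  list(value = model$alpha * d_1img^model$beta, outside_domain = outside)
}

#' Fit a power-law calibration to matched resolution points
#'
#' Least-squares fit of `log d_2img = log alpha + beta log d_1img`.
#'
#' @param d_1img,d_2img positive numeric vectors of matched resolutions
#'   (pixels), at least 2 distinct `d_1img` values.
#' @param provenance stored on the model.
#' @return a [calibration_model] with `domain = range(d_1img)`.
#' @export
fit_calibration_points <- function(d_1img, d_2img, provenance = list()) {
  stopifnot(length(d_1img) == length(d_2img), length(d_1img) >= 2L)
  if (any(d_1img <= 0) || any(d_2img <= 0)) stop("resolutions must be positive")
  if (length(unique(d_1img)) < 2L) stop("need at least 2 distinct d_1img values")
  fit <- lm(log(d_2img) ~ log(d_1img))
  m <- calibration_model(
    alpha = exp(coef(fit)[[1L]]),
    beta = coef(fit)[[2L]],
    domain = range(d_1img),
    provenance = provenance
  )
  ord <- order(d_1img)
  m$monotone <- m$beta > 0 && !is.unsorted(d_2img[ord])
  m
}

#' Fit the one-image FRC calibration from repeated image pairs
#'
#' For each pair (two registered images of the same field of view taken at
#' one pixel size), computes the two-image FRC resolution `d_2img` and the
#' mean of the two images' one-image FRC resolutions `d_1img`, then fits
#' `d_2img = alpha * d_1img^beta` in log-log space.  The calibration is
#' instrument-specific: it absorbs the systematic shift of the checkerboard
#' subsampling method.
#'
#' @param image_pairs list of `list(img_a, img_b, pixel_size_nm)`; at least
#'   2 pairs at distinct pixel sizes.
#' @param threshold FRC threshold.
#' @param window taper choice.
#' @return a [calibration_model]; `monotone = FALSE` flags non-monotone
#'   calibration data (the fit is still returned).
#' @export
fit_calibration <- function(image_pairs, threshold = 1 / 7, window = "hann") {
  if (length(image_pairs) < 2L) stop("need at least 2 image pairs")
  px <- vapply(image_pairs, function(p) as.numeric(p$pixel_size_nm), numeric(1))
  if (length(unique(px)) < 2L) stop("image pairs must span at least 2 distinct pixel sizes")
  d1 <- numeric(length(image_pairs))
  d2 <- numeric(length(image_pairs))
  for (i in seq_along(image_pairs)) {
    p <- image_pairs[[i]]
    two <- resolution_from_curve(
      compute_frc(p$img_a, p$img_b, window = window), threshold = threshold
    )
    one_a <- one_image_frc(p$img_a, threshold = threshold, window = window)
    one_b <- one_image_frc(p$img_b, threshold = threshold, window = window)
    d2[i] <- two$resolution_px
    d1[i] <- mean(c(one_a$resolution_px, one_b$resolution_px))
  }
  fit_calibration_points(
    d1, d2,
    provenance = list(pixel_sizes_nm = px, n_pairs = length(image_pairs),
                      d_1img = d1, d_2img = d2)
  )
}

#' Tiled local resolution map by one-image FRC
#'
#' Splits the image into non-overlapping square tiles anchored at the
#' top-left (partial edge tiles discarded), computes the one-image FRC
#' resolution on each, and summarizes the per-tile values.  Tiles with more
#' than half their pixels masked are excluded, so featureless or artifact
#' regions do not skew the map.
#'
#' @param image numeric matrix.
#' @param tile_px tile side, >= 32 and <= the smaller image dimension.
#' @param calibration optional [calibration_model].
#' @param mask optional exclusion mask (nonzero = excluded pixel).
#' @param threshold FRC threshold.
#' @param pixel_size_nm optional pixel size.
#' @param window taper choice.
#' @return a `resolution_map`: data.frame `tiles` (tile row/col, origin,
#'   `f_crossing`, `resolution_px`, `resolution_nm`, `status`, `included`)
#'   plus `summary` (mean, sd, median over included tiles, in px and nm)
#'   and the tile grid geometry.
#' @export
tiled_resolution <- function(image, tile_px, calibration = NULL, mask = NULL,
                             threshold = 1 / 7, pixel_size_nm = NULL,
                             window = "hann") {
  check_image(image)
  tile_px <- as.integer(tile_px)
  if (tile_px < 32L) stop("`tile_px` must be >= 32")
  if (tile_px > min(dim(image))) stop("`tile_px` exceeds the image size")
  if (!is.null(mask) && !all(dim(mask) == dim(image))) {
    stop("mask shape must match the image")
  }
  n_ty <- nrow(image) %/% tile_px
  n_tx <- ncol(image) %/% tile_px
  rows <- list()
  for (ty in seq_len(n_ty)) {
    for (tx in seq_len(n_tx)) {
      y0 <- (ty - 1L) * tile_px
      x0 <- (tx - 1L) * tile_px
      sel_y <- (y0 + 1L):(y0 + tile_px)
      sel_x <- (x0 + 1L):(x0 + tile_px)
      excluded <- !is.null(mask) &&
        mean(mask[sel_y, sel_x] != 0) > 0.5
      if (excluded) {
        rows[[length(rows) + 1L]] <- data.frame(
          tile_row = ty, tile_col = tx, y0 = y0, x0 = x0,
          f_crossing = NA_real_, resolution_px = NA_real_,
          resolution_nm = NA_real_, status = "masked", included = FALSE
        )
        next
      }
      r <- one_image_frc(image[sel_y, sel_x], calibration = calibration,
                         threshold = threshold, pixel_size_nm = pixel_size_nm,
                         window = window)
      rows[[length(rows) + 1L]] <- data.frame(
        tile_row = ty, tile_col = tx, y0 = y0, x0 = x0,
        f_crossing = r$f_crossing, resolution_px = r$resolution_px,
        resolution_nm = r$resolution_nm, status = r$status, included = TRUE
      )
    }
  }
  tiles <- do.call(rbind, rows)
  inc <- tiles$included
  if (!any(inc)) stop("no tiles included (all masked)")
  v <- tiles$resolution_px[inc]
  summary <- list(
    n_tiles = sum(inc),
    mean_px = mean(v), sd_px = sd(v), median_px = median(v),
    mean_nm = mean(tiles$resolution_nm[inc]),
    median_nm = median(tiles$resolution_nm[inc])
  )
  structure(
    list(tiles = tiles, summary = summary, tile_px = tile_px,
         calibrated = !is.null(calibration)),
    class = "resolution_map"
  )
}

#' @export
print.resolution_map <- function(x, ...) {
  cat(sprintf(
    "<resolution_map> tile %d px, %d tiles included: median %.3f px (mean %.3f, sd %.3f)\n",
    x$tile_px, x$summary$n_tiles, x$summary$median_px, x$summary$mean_px,
    x$summary$sd_px
  ))
  invisible(x)
}

# Distribution comparison given named per-size resolution samples; the
# Kruskal-Wallis H-test checks equality of the group medians.
tile_size_report <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  stats_per <- lapply(samples, function(v) {
    list(n = length(v), min = min(v), max = max(v), median = median(v))
  })
  medians <- vapply(stats_per, `[[`, numeric(1), "median")
  kw <- kruskal.test(samples)
  list(
    per_size = stats_per,
    medians = medians,
    max_median_diff_px = max(medians) - min(medians),
    kruskal_H = unname(kw$statistic),
    p_value = kw$p.value
  )
}

#' Compare per-tile resolution distributions across tile sizes
#'
#' Runs [tiled_resolution()] for each tile size and tests whether the
#' per-tile resolution distributions share one median (Kruskal-Wallis
#' H-test).  On a homogeneous image the tile size should not matter; a
#' small p-value indicates the tiling choice is influencing the resolution
#' estimate.
#'
#' @param image numeric matrix.
#' @param tile_sizes integer vector of at least 2 tile sides.
#' @param calibration optional [calibration_model].
#' @param threshold FRC threshold.
#' @param pixel_size_nm optional pixel size.
#' @param mask optional exclusion mask.
#' @param window taper choice.
#' @return list with per-size min/max/median (`per_size`, named by tile
#'   size), `max_median_diff_px`, `kruskal_H`, `p_value`, and the raw
#'   `samples`.
#' @export
compare_tile_sizes <- function(image, tile_sizes, calibration = NULL,
                               threshold = 1 / 7, pixel_size_nm = NULL,
                               mask = NULL, window = "hann") {
  if (length(tile_sizes) < 2L) stop("need at least 2 tile sizes")
  samples <- lapply(tile_sizes, function(tp) {
    m <- tiled_resolution(image, tp, calibration = calibration, mask = mask,
                          threshold = threshold, pixel_size_nm = pixel_size_nm,
                          window = window)
    m$tiles$resolution_px[m$tiles$included]
  })
  names(samples) <- paste0("tile_", tile_sizes)
  rep <- tile_size_report(samples)
  rep$samples <- samples
  rep
}
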