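#' Seeded textured test image
#'
#' Emulates the local contrast of an SEM slice: randomly placed smoothed
#' blobs of mixed polarity plus additive Gaussian noise, normalized to zero
#' mean and unit standard deviation before the noise is added.  The default
#' density gives hundreds of distinctive landmarks on a 512x512 frame.
#' Purely a function of `(parameters, seed)`: the same call reproduces the
#' image bitwise.
#'
#' @param shape `c(height, width)`, at least 64x64.
#' @param blob_density expected blobs per pixel.
#' @param blob_sigma Gaussian radius of a blob (px).
#' @param noise_sigma additive noise standard deviation (image is unit-sd
#'   before noise).
#' @param seed RNG seed.
#' @return numeric matrix.
#' @export
make_textured_image <- function(shape = c(512L, 512L), blob_density = 0.005,
                                blob_sigma = 2.5, noise_sigma = 0.05,
                                seed = 0L) {
  stopifnot(length(shape) == 2L, all(shape >= 64L))
  ny <- as.integer(shape[1L]); nx <- as.integer(shape[2L])
  with_seed(seed, {
    n_blobs <- max(1L, round(blob_density * ny * nx))
    impulses <- matrix(0, ny, nx)
    iy <- sample.int(ny, n_blobs, replace = TRUE)
    ix <- sample.int(nx, n_blobs, replace = TRUE)
    amp <- runif(n_blobs, 0.5, 1.5) * sample(c(-1, 1), n_blobs, replace = TRUE)
    for (i in seq_len(n_blobs)) {
      impulses[iy[i], ix[i]] <- impulses[iy[i], ix[i]] + amp[i]
    }
    img <- gblur_mat(impulses, blob_sigma)
    img <- (img - mean(img)) / sd(img)
    if (noise_sigma > 0) img <- img + noise_sigma * matrix(rnorm(ny * nx), ny, nx)
    img
  })
}

# Builds an affine2d from named per-pair parameters, restricted to `spec`.
affine_from_params <- function(spec, p) {
  allowed <- c(
    if (spec$translate || spec$affine) c("tx", "ty"),
    if (spec$shear_x || spec$affine) "shear_x",
    if (spec$shear_y || spec$affine) "shear_y",
    if (spec$stretch_x || spec$affine) "stretch_x",
    if (spec$stretch_y || spec$affine) "stretch_y",
    if (spec$scale_uniform) "scale",
    if (spec$rotate) "angle"
  )
  bad <- setdiff(names(p), allowed)
  if (length(bad)) {
    stop(sprintf("schedule parameter(s) outside the spec family: %s",
                 paste(bad, collapse = ", ")))
  }
  g <- function(nm, d) if (!is.null(p[[nm]])) p[[nm]] else d
  A <- diag(2)
  if (!is.null(p$angle)) {
    th <- p$angle
    A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  }
  A[1, 1] <- A[1, 1] * g("stretch_x", 1) * g("scale", 1)
  A[2, 2] <- A[2, 2] * g("stretch_y", 1) * g("scale", 1)
  A[1, 2] <- A[1, 2] + g("shear_x", 0)
  A[2, 1] <- A[2, 1] + g("shear_y", 0)
  affine2d(A, c(g("tx", 0), g("ty", 0)))
}

#' Seeded misaligned serial stack with known ground truth
#'
#' Slice 1 is a textured base image; slice `k` is the (slightly evolved)
#' texture resampled through the inverse of the known cumulative transform,
#' so aligning slice `k` back to the reference frame should recover that
#' cumulative transform.  Texture evolution between slices is a 2%
#' amplitude smooth perturbation, mimicking the similar-but-not-identical
#' appearance of consecutive physical sections.
#'
#' @param n_slices number of slices (>= 2).
#' @param spec a [transform_spec]; schedule parameters must stay within it.
#' @param param_schedule list of length `n_slices - 1`; element `k` is a
#'   named list of per-pair parameters (`tx`, `ty`, `shear_x`, `shear_y`,
#'   `stretch_x`, `stretch_y`, `scale`, `angle`) describing the map from
#'   slice `k+1` coordinates into slice `k`'s frame.
#' @param shape slice shape.
#' @param seed RNG seed.
#' @param evolve_amplitude slice-to-slice texture perturbation amplitude
#'   (fraction of image sd).
#' @param ... forwarded to [make_textured_image()].
#' @return list with `stack` (an [image_stack]) and `record` (ground-truth
#'   record: seed, parameters, pairwise and cumulative transforms).
#' @export
make_misaligned_stack <- function(n_slices, spec, param_schedule,
                                  shape = c(256L, 256L), seed = 0L,
                                  evolve_amplitude = 0.02, ...) {
  stopifnot(n_slices >= 2L, length(param_schedule) == n_slices - 1L)
  pairwise <- lapply(param_schedule, function(p) affine_from_params(spec, p))
  cumulative <- compose_transforms(pairwise)
  base <- make_textured_image(shape = shape, seed = seed, ...)
  data <- array(0, dim = c(n_slices, shape[1L], shape[2L]))
  with_seed(seed + 1L, {
    tex <- base
    for (k in seq_len(n_slices)) {
      if (k > 1L) {
        pert <- gblur_mat(matrix(rnorm(prod(shape)), shape[1L], shape[2L]), 4)
        pert <- pert / sd(pert)
        tex <- tex + evolve_amplitude * sd(tex) * pert
      }
      data[k, , ] <- if (k == 1L) tex else {
        apply_transform(tex, invert_transform(cumulative[[k]]))
      }
    }
  })
  record <- list(
    generator = "make_misaligned_stack",
    seed = seed,
    shape = shape,
    n_slices = n_slices,
    param_schedule = param_schedule,
    pairwise = pairwise,
    cumulative = cumulative,
    evolve_amplitude = evolve_amplitude
  )
  list(stack = image_stack(data), record = record)
}

#' Seeded synthetic charging-artifact image with known tails
#'
#' A flat background with dark filled ellipses (the charging centres,
#' labelled in the returned mask) and, on every row crossing an ellipse,
#' additive shifted-logistic tails of the exact [sigmoid_tail()] form
#' extending left and right of the ellipse, with per-side amplitudes and
#' widths (asymmetry allowed); plus Gaussian noise.  Ellipses must not
#' overlap so the fitting windows stay well defined.
#'
#' @param shape `c(height, width)`.
#' @param centers data.frame (or list of lists) with columns `x`, `y`,
#'   `rx`, `ry`: ellipse centres and radii in pixels (0-based centres).
#' @param tail_params list, one element per centre, each
#'   `list(left = c(amplitude, width), right = c(amplitude, width))`.
#' @param background_level flat background intensity.
#' @param center_depth intensity offset of the ellipse interiors (negative
#'   = dark).
#' @param noise_sigma Gaussian noise sd.
#' @param seed RNG seed.
#' @return list with `image`, `mask` (integer labels, one per centre) and
#'   `record` (all applied parameters).
#' @export
make_charging_image <- function(shape = c(256L, 256L), centers,
                                tail_params, background_level = 100,
                                center_depth = -50, noise_sigma = 2,
                                seed = 0L) {
  ny <- as.integer(shape[1L]); nx <- as.integer(shape[2L])
  centers <- as.data.frame(centers)
  stopifnot(all(c("x", "y", "rx", "ry") %in% names(centers)),
            length(tail_params) == nrow(centers))
  if (any(centers$x - centers$rx < 0 | centers$x + centers$rx > nx - 1 |
          centers$y - centers$ry < 0 | centers$y + centers$ry > ny - 1)) {
    stop("ellipse extends outside the image bounds")
  }
  X <- matrix(rep(0:(nx - 1L), each = ny), ny, nx)
  Y <- matrix(rep(0:(ny - 1L), times = nx), ny, nx)
  mask <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(centers))) {
    inside <- ((X - centers$x[i]) / centers$rx[i])^2 +
      ((Y - centers$y[i]) / centers$ry[i])^2 <= 1
    if (any(mask[inside] != 0L)) stop("ellipses overlap")
    mask[inside] <- i
  }
  img <- matrix(background_level, ny, nx)
  img[mask != 0L] <- background_level + center_depth
  for (i in seq_len(nrow(centers))) {
    tp <- tail_params[[i]]
    rows <- which(apply(mask == i, 1L, any))
    for (r in rows) {
      seg <- range(which(mask[r, ] == i)) - 1L # 0-based columns
      if (seg[1L] > 0L) {
        xs <- 0:(seg[1L] - 1L)
        left <- sigmoid_tail_model("left", amplitude = tp$left[1L],
                                   center = seg[1L], width = tp$left[2L])
        sel <- xs + 1L
        free <- mask[r, sel] == 0L
        img[r, sel[free]] <- img[r, sel[free]] + sigmoid_tail(xs[free], left)
      }
      if (seg[2L] < nx - 1L) {
        xs <- (seg[2L] + 1L):(nx - 1L)
        right <- sigmoid_tail_model("right", amplitude = tp$right[1L],
                                    center = seg[2L], width = tp$right[2L])
        sel <- xs + 1L
        free <- mask[r, sel] == 0L
        img[r, sel[free]] <- img[r, sel[free]] + sigmoid_tail(xs[free], right)
      }
    }
  }
  if (noise_sigma > 0) {
    img <- img + with_seed(seed, noise_sigma * matrix(rnorm(ny * nx), ny, nx))
  }
  record <- list(
    generator = "make_charging_image", seed = seed, shape = c(ny, nx),
    centers = centers, tail_params = tail_params,
    background_level = background_level, center_depth = center_depth,
    noise_sigma = noise_sigma
  )
  list(image = img, mask = mask, record = record)
}

#' Seeded band-limited image pair with known spectral cutoff
#'
#' The ground truth is white Gaussian noise hard low-pass filtered at
#' `cutoff_norm` (fraction of the Nyquist ring; spectral power above the
#' cutoff is exactly zero), normalized to unit standard deviation.  The two
#' outputs are the ground truth plus independent Gaussian noise
#' realizations at the stated amplitude signal-to-noise ratio, emulating
#' two independently acquired images of one field of view.
#'
#' @param shape square `c(n, n)`, power of two preferred.
#' @param cutoff_norm cutoff in `(0, 1)` (1 = Nyquist).
#' @param snr amplitude SNR `sd(signal) / sd(noise)`; `Inf` gives two
#'   identical noise-free images.
#' @param seed RNG seed.
#' @return list with `img_a`, `img_b`, `ground_truth` and `record`.
#' @export
make_bandlimited_pair <- function(shape = c(512L, 512L), cutoff_norm = 0.5,
                                  snr = 5, seed = 0L) {
  stopifnot(length(shape) == 2L, shape[1L] == shape[2L])
  n <- as.integer(shape[1L])
  if (n %% 2L != 0L) stop("shape must be even (power of two preferred)")
  stopifnot_scalar_num(cutoff_norm, "cutoff_norm", positive = TRUE)
  if (cutoff_norm > 1) stop("`cutoff_norm` must be in (0, 1]")
  with_seed(seed, {
    white <- matrix(rnorm(n * n), n, n)
    f <- c(0:(n %/% 2 - 1), -(n %/% 2), -((n %/% 2 - 1):1))
    fx <- matrix(rep(f, each = n), n, n)
    fy <- matrix(rep(f, times = n), n, n)
    radius <- sqrt(fx^2 + fy^2) / (n %/% 2)
    keep <- radius <= cutoff_norm
    Fw <- fft(white) * keep
    gt <- Re(fft(Fw, inverse = TRUE)) / (n * n)
    gt <- (gt - mean(gt)) / sd(gt)
    if (is.finite(snr)) {
      na <- matrix(rnorm(n * n), n, n) / snr
      nb <- matrix(rnorm(n * n), n, n) / snr
      img_a <- gt + na
      img_b <- gt + nb
    } else {
      img_a <- gt
      img_b <- gt
    }
    record <- list(
      generator = "make_bandlimited_pair", seed = seed, shape = c(n, n),
      cutoff_norm = cutoff_norm, snr = snr
    )
    list(img_a = img_a, img_b = img_b, ground_truth = gt, record = record)
  })
}
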