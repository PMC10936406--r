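#' Constrained transformation family specification
#'
#' Describes which degrees of freedom of a 2D affine map are free during
#' fitting.  The physical motivation: serial FIB/SEM slices are distorted by
#' drift (translation), by shear along the fast-scan x-axis, and by stretch
#' along the slow-scan y-axis -- but not by rotation, so allowing rotation
#' lets the optimizer introduce a nonphysical twist of the volume.
#'
#' Supported combinations: any subset of
#' `{translate, shear_x, shear_y, stretch_x, stretch_y, scale_uniform}`
#' (solved by linear least squares); `{translate?, rotate, scale_uniform?}`
#' (closed-form Procrustes); `affine = TRUE` frees all six degrees of
#' freedom and overrides the other flags.  `rotate` may not be combined with
#' shear or stretch, and `scale_uniform` excludes `stretch_x`/`stretch_y`.
#'
#' @param translate,rotate,shear_x,shear_y,stretch_x,stretch_y,scale_uniform,affine
#'   logical flags.
#' @return a `transform_spec` object.
#' @export
transform_spec <- function(translate = FALSE, rotate = FALSE,
                           shear_x = FALSE, shear_y = FALSE,
                           stretch_x = FALSE, stretch_y = FALSE,
                           scale_uniform = FALSE, affine = FALSE) {
  flags <- list(
    translate = isTRUE(translate), rotate = isTRUE(rotate),
    shear_x = isTRUE(shear_x), shear_y = isTRUE(shear_y),
    stretch_x = isTRUE(stretch_x), stretch_y = isTRUE(stretch_y),
    scale_uniform = isTRUE(scale_uniform), affine = isTRUE(affine)
  )
  if (flags$affine) {
    flags[c("translate", "rotate", "shear_x", "shear_y",
            "stretch_x", "stretch_y", "scale_uniform")] <- FALSE
  } else {
    if (flags$rotate && (flags$shear_x || flags$shear_y ||
                         flags$stretch_x || flags$stretch_y)) {
      stop("`rotate` may only be combined with `translate` and `scale_uniform`")
    }
    if (flags$scale_uniform && (flags$stretch_x || flags$stretch_y)) {
      stop("`scale_uniform` excludes `stretch_x`/`stretch_y`")
    }
  }
  structure(flags, class = "transform_spec")
}

#' Parse a transform spec from a comma-separated string
#'
#' e.g. `"translate,shear_x,stretch_y"` or `"affine"`.
#' @param s character scalar.
#' @return a [transform_spec].
#' @export
parse_transform_spec <- function(s) {
  parts <- trimws(strsplit(s, ",")[[1L]])
  known <- c("translate", "rotate", "shear_x", "shear_y",
             "stretch_x", "stretch_y", "scale_uniform", "affine")
  bad <- setdiff(parts, known)
  if (length(bad)) stop(sprintf("unknown transform component(s): %s", paste(bad, collapse = ", ")))
  do.call(transform_spec, as.list(stats::setNames(rep(TRUE, length(parts)), parts)))
}

# Number of free parameters of a spec.
spec_n_params <- function(spec) {
  if (spec$affine) return(6L)
  n <- 0L
  if (spec$translate) n <- n + 2L
  if (spec$rotate) n <- n + 1L
  if (spec$shear_x) n <- n + 1L
  if (spec$shear_y) n <- n + 1L
  if (spec$stretch_x) n <- n + 1L
  if (spec$stretch_y) n <- n + 1L
  if (spec$scale_uniform) n <- n + 1L
  n
}

#' 2D affine transform
#'
#' Maps a point `r = (x, y)` (x = column, y = row, 0-based, pixel units) to
#' `r' = A r + b`.
#'
#' @param A 2x2 numeric matrix.
#' @param b length-2 translation `(b1, b2)` in pixels (x then y).
#' @return an `affine2d` object.
#' @export
affine2d <- function(A = diag(2), b = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  b <- as.numeric(b)
  stopifnot(length(b) == 2L, all(is.finite(A)), all(is.finite(b)))
  structure(list(A = A, b = b), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> A = [", sprintf("%.6g", x$A[1, 1]), sprintf("%.6g", x$A[1, 2]), ";",
      sprintf("%.6g", x$A[2, 1]), sprintf("%.6g", x$A[2, 2]), "], b = (",
      sprintf("%.6g", x$b[1]), ",", sprintf("%.6g", x$b[2]), ")\n")
  invisible(x)
}

#' Identity affine transform
#' @return an [affine2d] with `A = I`, `b = 0`.
#' @export
identity_transform <- function() affine2d()

#' Invert an affine transform
#' @param t an [affine2d].
#' @return the inverse transform.
#' @export
invert_transform <- function(t) {
  Ai <- tryCatch(solve(t$A), error = function(e) stop("transform matrix is singular"))
  affine2d(Ai, -Ai %*% t$b)
}

#' Apply an affine transform to point coordinates
#' @param t an [affine2d].
#' @param xy n x 2 matrix of `(x, y)` points.
#' @return n x 2 matrix of mapped points.
#' @export
transform_points <- function(t, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  sweep(xy %*% t(t$A), 2L, t$b, "+")
}

# Composition: (s o t)(r) = s(t(r)).
compose2 <- function(s, t) affine2d(s$A %*% t$A, s$A %*% t$b + s$b)

#' Cumulative composition of pairwise slice transforms
#'
#' Given the list of pairwise transforms (element `k` maps slice `k+1`
#' coordinates into slice `k`'s frame), returns the cumulative transforms to
#' the reference slice: element 1 is the identity and element `k` maps slice
#' `k` into slice 1's frame, i.e. `cumulative[k] = pairwise[1] o ... o
#' pairwise[k-1]`.  Composition is exact matrix arithmetic.
#'
#' @param pairwise list of [affine2d] of length `n - 1`.
#' @return list of [affine2d] of length `n`.
#' @export
compose_transforms <- function(pairwise) {
  cumulative <- vector("list", length(pairwise) + 1L)
  cumulative[[1L]] <- identity_transform()
  for (k in seq_along(pairwise)) {
    cumulative[[k + 1L]] <- compose2(cumulative[[k]], pairwise[[k]])
  }
  cumulative
}

#' Fit the best transform of a constrained family to landmark matches
#'
#' Minimizes the sum of squared distances `sum_i || A r_i + b - r'_i ||^2`
#' over the transforms in the family described by `spec`.  Families without
#' rotation are linear in their parameters and solved exactly by least
#' squares; rotation families use the closed-form 2D Procrustes solution.
#' Matrix entries not enabled by the spec equal their identity values
#' exactly (bit-exact), by construction.
#'
#' @param matches a [match_set].
#' @param spec a [transform_spec].
#' @return an [affine2d] with attribute `residual_rms` (root mean squared
#'   residual distance in pixels).
#' @export
fit_constrained_transform <- function(matches, spec) {
  stopifnot(inherits(matches, "match_set"), inherits(spec, "transform_spec"))
  n <- nrow(matches$points_src)
  n_par <- spec_n_params(spec)
  need <- max(1L, ceiling(n_par / 2))
  if (n < need) {
    stop(sprintf("need at least %d matches for this spec, got %d", need, n))
  }
  src <- matches$points_src
  dst <- matches$points_dst
  x <- src[, 1L]; y <- src[, 2L]

  if (spec$rotate) {
    t <- fit_procrustes(src, dst, translate = spec$translate,
                        scale = spec$scale_uniform)
  } else if (spec$affine || n_par > 0L) {
    if (spec$affine) {
      if (n < 3L) stop("affine fit needs at least 3 matches")
      spec_eff <- list(translate = TRUE, shear_x = TRUE, shear_y = TRUE,
                       stretch_x = TRUE, stretch_y = TRUE, scale_uniform = FALSE)
    } else {
      spec_eff <- spec
    }
    # free parameters th: columns of the stacked design matrix; rows are the
    # x-equations then the y-equations, with the identity part moved to the
    # right-hand side:  dx = d11*x + a12*y + s*x + b1 ; dy = a21*x + d22*y + s*y + b2
    cols <- list(); names_par <- character(0)
    zero <- numeric(n)
    add <- function(name, cx, cy) {
      cols[[length(cols) + 1L]] <<- c(cx, cy)
      names_par[length(names_par) + 1L] <<- name
    }
    if (spec_eff$stretch_x) add("d11", x, zero)
    if (spec_eff$shear_x) add("a12", y, zero)
    if (spec_eff$shear_y) add("a21", zero, x)
    if (spec_eff$stretch_y) add("d22", zero, y)
    if (isTRUE(spec_eff$scale_uniform)) add("s", x, y)
    if (spec_eff$translate) {
      add("b1", rep(1, n), zero)
      add("b2", zero, rep(1, n))
    }
    rhs <- c(dst[, 1L] - x, dst[, 2L] - y)
    if (length(cols) == 0L) {
      t <- identity_transform()
    } else {
      X <- do.call(cbind, cols)
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        stop("rank-deficient system: matches do not determine the enabled parameters (collinear points?)")
      }
      th <- as.numeric(qr.coef(qrX, rhs))
      names(th) <- names_par
      A <- diag(2); b <- c(0, 0)
      g <- function(nm) if (nm %in% names_par) th[[nm]] else 0
      A[1, 1] <- 1 + g("d11") + g("s")
      A[1, 2] <- g("a12")
      A[2, 1] <- g("a21")
      A[2, 2] <- 1 + g("d22") + g("s")
      b <- c(g("b1"), g("b2"))
      t <- affine2d(A, b)
    }
  } else {
    t <- identity_transform()
  }
  res <- transform_points(t, src) - dst
  attr(t, "residual_rms") <- sqrt(mean(rowSums(res^2)))
  t
}

# Closed-form 2D Procrustes (rigid / similarity) fit.
fit_procrustes <- function(src, dst, translate = TRUE, scale = FALSE) {
  if (translate) {
    cs <- colMeans(src); cd <- colMeans(dst)
  } else {
    cs <- c(0, 0); cd <- c(0, 0)
  }
  ps <- sweep(src, 2L, cs)
  pd <- sweep(dst, 2L, cd)
  num_sin <- sum(ps[, 1L] * pd[, 2L] - ps[, 2L] * pd[, 1L])
  num_cos <- sum(ps[, 1L] * pd[, 1L] + ps[, 2L] * pd[, 2L])
  theta <- atan2(num_sin, num_cos)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  s <- if (scale) {
    denom <- sum(ps^2)
    if (denom == 0) stop("degenerate point set for similarity fit")
    sum(pd * (ps %*% t(R))) / denom
  } else {
    1
  }
  A <- s * R
  b <- cd - A %*% cs
  affine2d(A, b)
}

#' Resample an image through an affine transform
#'
#' Each output pixel `(x, y)` is sampled from the input at the
#' inverse-mapped location `A^-1 ((x, y) - b)` with the chosen
#' interpolation; locations outside the input are set to `fill_value`.
#' Output has the shape of the input.  Coordinates are 0-based with x =
#' column, y = row, origin at the top-left pixel centre.
#'
#' @param image numeric matrix `[row, column]`.
#' @param t an [affine2d]: the map from input coordinates to output
#'   coordinates.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @param fill_value value for out-of-bounds pixels; default is the image
#'   median (avoids dark borders skewing later statistics).
#' @return numeric matrix of the same shape.
#' @export
apply_transform <- function(image, t, interpolation = c("bilinear", "nearest"),
                            fill_value = NULL) {
  check_image(image)
  interpolation <- match.arg(interpolation)
  if (is.null(fill_value)) fill_value <- median(image)
  ti <- invert_transform(t)
  ny <- nrow(image); nx <- ncol(image)
  xo <- rep(0:(nx - 1L), each = ny)
  yo <- rep(0:(ny - 1L), times = nx)
  xi <- ti$A[1, 1] * xo + ti$A[1, 2] * yo + ti$b[1]
  yi <- ti$A[2, 1] * xo + ti$A[2, 2] * yo + ti$b[2]
  out <- rep(fill_value, nx * ny)
  if (interpolation == "nearest") {
    xr <- round(xi); yr <- round(yi)
    ok <- xr >= 0 & xr <= nx - 1L & yr >= 0 & yr <= ny - 1L
    out[ok] <- image[cbind(yr[ok] + 1L, xr[ok] + 1L)]
  } else {
    x0 <- floor(xi); y0 <- floor(yi)
    fx <- xi - x0; fy <- yi - y0
    ok <- x0 >= 0 & x0 <= nx - 2L & y0 >= 0 & y0 <= ny - 2L
    # include locations exactly on the last row/column
    edgex <- x0 == nx - 1L & fx < 1e-9
    edgey <- y0 == ny - 1L & fy < 1e-9
    x0e <- ifelse(edgex, x0 - 1, x0); fxe <- ifelse(edgex, 1, fx)
    y0e <- ifelse(edgey, y0 - 1, y0); fye <- ifelse(edgey, 1, fy)
    ok <- (x0e >= 0 & x0e <= nx - 2L & y0e >= 0 & y0e <= ny - 2L)
    yk <- y0e[ok] + 1L; xk <- x0e[ok] + 1L
    v00 <- image[cbind(yk, xk)]
    v01 <- image[cbind(yk, xk + 1L)]
    v10 <- image[cbind(yk + 1L, xk)]
    v11 <- image[cbind(yk + 1L, xk + 1L)]
    fxo <- fxe[ok]; fyo <- fye[ok]
    out[ok] <- (1 - fyo) * ((1 - fxo) * v00 + fxo * v01) +
      fyo * ((1 - fxo) * v10 + fxo * v11)
  }
  matrix(out, ny, nx)
}
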