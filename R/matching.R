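#' Paired landmark matches between two images
#'
#' @param points_src n x 2 matrix of `(x, y)` coordinates on the source
#'   image (0-based pixels).
#' @param points_dst n x 2 matrix of matched coordinates on the target
#'   image.
#' @param scores per-match quality score (higher is better).
#' @return a `match_set` object.
#' @export
match_set <- function(points_src, points_dst, scores = NULL) {
  points_src <- matrix(as.numeric(points_src), ncol = 2L)
  points_dst <- matrix(as.numeric(points_dst), ncol = 2L)
  if (nrow(points_src) != nrow(points_dst)) {
    stop("source and target point lists must have equal length")
  }
  if (is.null(scores)) scores <- rep(1, nrow(points_src))
  structure(
    list(points_src = points_src, points_dst = points_dst,
         scores = as.numeric(scores)),
    class = "match_set"
  )
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set> %d matches\n", nrow(x$points_src)))
  invisible(x)
}

n_matches <- function(m) nrow(m$points_src)

subset_matches <- function(m, idx) {
  match_set(m$points_src[idx, , drop = FALSE],
            m$points_dst[idx, , drop = FALSE],
            m$scores[idx])
}

#' Landmark detector settings
#'
#' Settings of the deterministic landmark pipeline used by
#' [detect_and_match()]: a Shi-Tomasi corner response (minimum eigenvalue of
#' the smoothed structure tensor) with non-maximum suppression, followed by
#' normalized square patch descriptors matched by nearest neighbour with a
#' Lowe ratio test.
#'
#' @param n_keypoints maximum keypoints kept per image (by response).
#' @param sigma_smooth Gaussian smoothing (px) applied before gradients and
#'   used for the descriptor patches.
#' @param sigma_integrate structure-tensor integration scale (px).
#' @param patch_radius descriptor patch half-width (px); descriptors are
#'   `(2r+1)^2` mean-removed, L2-normalized patches.
#' @param ratio Lowe ratio threshold (best/second-best descriptor distance).
#' @param mutual require the match to be the mutual nearest neighbour.
#' @param response_rel minimum corner response relative to the image
#'   maximum.
#' @return a `detector_params` list.
#' @export
detector_params <- function(n_keypoints = 1500L, sigma_smooth = 1.2,
                            sigma_integrate = 2.0, patch_radius = 7L,
                            ratio = 0.75, mutual = TRUE,
                            response_rel = 0.005) {
  structure(
    list(n_keypoints = as.integer(n_keypoints), sigma_smooth = sigma_smooth,
         sigma_integrate = sigma_integrate,
         patch_radius = as.integer(patch_radius),
         ratio = ratio, mutual = isTRUE(mutual), response_rel = response_rel),
    class = "detector_params"
  )
}

# Shi-Tomasi keypoints + normalized patch descriptors for one image.
# Returns list(xy = n x 2 (0-based), desc = n x d) or zero-row matrices.
detect_keypoints <- function(img, params) {
  ny <- nrow(img); nx <- ncol(img)
  s <- sd(img)
  empty <- list(xy = matrix(numeric(0), 0, 2), desc = matrix(numeric(0), 0, 0))
  if (s == 0) return(empty)
  g <- gblur_mat((img - mean(img)) / s, params$sigma_smooth)
  gx <- (g[, c(2:nx, nx)] - g[, c(1, 1:(nx - 1))]) / 2
  gy <- (g[c(2:ny, ny), ] - g[c(1, 1:(ny - 1)), ]) / 2
  Sxx <- gblur_mat(gx * gx, params$sigma_integrate)
  Syy <- gblur_mat(gy * gy, params$sigma_integrate)
  Sxy <- gblur_mat(gx * gy, params$sigma_integrate)
  resp <- 0.5 * ((Sxx + Syy) - sqrt((Sxx - Syy)^2 + 4 * Sxy^2))
  mar <- params$patch_radius + 3L
  if (2L * mar + 2L >= min(ny, nx)) return(empty)
  keep <- matrix(FALSE, ny, nx)
  keep[(mar + 1L):(ny - mar), (mar + 1L):(nx - mar)] <- TRUE
  # strict 8-neighbour local maxima
  shifted_max <- matrix(-Inf, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- pmin(pmax(1:ny + dy, 1L), ny)
    xs <- pmin(pmax(1:nx + dx, 1L), nx)
    shifted_max <- pmax(shifted_max, resp[ys, xs])
  }
  is_max <- keep & (resp > shifted_max) & (resp > params$response_rel * max(resp))
  idx <- which(is_max)
  if (length(idx) == 0L) return(empty)
  ord <- order(resp[idx], decreasing = TRUE)
  idx <- idx[ord[seq_len(min(length(ord), params$n_keypoints))]]
  row <- (idx - 1L) %% ny + 1L
  col <- (idx - 1L) %/% ny + 1L
  r <- params$patch_radius
  off <- as.matrix(expand.grid(dy = -r:r, dx = -r:r))
  # gather patches: n_kp x (2r+1)^2
  desc <- matrix(0, length(idx), nrow(off))
  for (j in seq_len(nrow(off))) {
    desc[, j] <- g[cbind(row + off[j, 1L], col + off[j, 2L])]
  }
  desc <- desc - rowMeans(desc)
  nrm <- sqrt(rowSums(desc^2))
  nrm[nrm == 0] <- 1
  desc <- desc / nrm
  list(xy = cbind(col - 1, row - 1), desc = desc)
}

#' Detect landmarks on two images and match them
#'
#' Detects corner landmarks on both images, describes each by a normalized
#' intensity patch, and matches descriptors by nearest neighbour with a
#' Lowe ratio test (optionally requiring mutual nearest neighbours).  The
#' whole pipeline is deterministic for fixed inputs and settings.  Images
#' with no detectable landmarks yield an empty match set, not an error.
#'
#' @param img_a,img_b numeric matrices of the same shape.
#' @param params a [detector_params].
#' @return a [match_set]; `points_src` are on `img_a`, `points_dst` on
#'   `img_b`; scores are `1 - ratio` (higher = more distinctive).
#' @export
detect_and_match <- function(img_a, img_b, params = detector_params()) {
  check_image(img_a, "img_a"); check_image(img_b, "img_b")
  if (!all(dim(img_a) == dim(img_b))) stop("images must have the same shape")
  ka <- detect_keypoints(img_a, params)
  kb <- detect_keypoints(img_b, params)
  if (nrow(ka$xy) == 0L || nrow(kb$xy) < 2L) {
    return(match_set(matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2)))
  }
  # squared descriptor distances
  cross <- ka$desc %*% t(kb$desc)
  d2 <- outer(rowSums(ka$desc^2), rowSums(kb$desc^2), "+") - 2 * cross
  d2[d2 < 0] <- 0
  best <- max.col(-d2, ties.method = "first")
  d1 <- d2[cbind(seq_len(nrow(d2)), best)]
  d2nd <- apply(replace(d2, cbind(seq_len(nrow(d2)), best), Inf), 1L, min)
  ratio <- sqrt(d1) / pmax(sqrt(d2nd), .Machine$double.eps)
  ok <- ratio < params$ratio
  if (params$mutual) {
    best_b <- max.col(-t(d2), ties.method = "first")
    ok <- ok & (best_b[best] == seq_len(nrow(d2)))
  }
  if (!any(ok)) {
    return(match_set(matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2)))
  }
  match_set(ka$xy[ok, , drop = FALSE], kb$xy[best[ok], , drop = FALSE],
            scores = 1 - ratio[ok])
}

#' Percentile outlier filter on match displacements
#'
#' Computes the displacement `d_i = r'_i - r_i` of every match and keeps
#' matches whose x- and y-components both lie within the `[q, 100 - q]`
#' percentile interval of their respective component distributions.
#' `q = 0` returns the input unchanged.
#'
#' @param matches a nonempty [match_set].
#' @param q percent, in `[0, 50)`.
#' @return the filtered [match_set].
#' @export
filter_matches_percentile <- function(matches, q = 5) {
  stopifnot(inherits(matches, "match_set"))
  if (n_matches(matches) == 0L) stop("no matches to filter")
  stopifnot_scalar_num(q, "q")
  if (q < 0 || q >= 50) stop("`q` must be in [0, 50)")
  if (q == 0) return(matches)
  d <- matches$points_dst - matches$points_src
  lo <- apply(d, 2L, quantile, probs = q / 100)
  hi <- apply(d, 2L, quantile, probs = 1 - q / 100)
  keep <- d[, 1L] >= lo[1L] & d[, 1L] <= hi[1L] &
    d[, 2L] >= lo[2L] & d[, 2L] <= hi[2L]
  subset_matches(matches, keep)
}

#' RANSAC outlier filter under a constrained transform model
#'
#' Repeatedly fits the constrained model to a minimal random sample of
#' matches and counts matches whose residual `||A r + b - r'||` is below
#' `inlier_tol_px`; returns the largest consensus set found.  Reproducible
#' for a fixed seed.  The minimal sample size is
#' `max(3, ceiling(n_params / 2))`.
#'
#' @param matches a [match_set].
#' @param spec a [transform_spec] (the model fitted to each sample).
#' @param inlier_tol_px inlier residual tolerance in pixels.
#' @param n_iter number of random samples.
#' @param seed RNG seed.
#' @return the consensus [match_set], with attribute `n_inliers`.
#' @export
filter_matches_ransac <- function(matches, spec, inlier_tol_px = 2,
                                  n_iter = 1000L, seed = 0L) {
  stopifnot(inherits(matches, "match_set"), inherits(spec, "transform_spec"))
  n <- n_matches(matches)
  m <- max(3L, as.integer(ceiling(spec_n_params(spec) / 2)))
  if (n < m) {
    stop(sprintf(
      "RANSAC needs at least %d matches for this spec but only %d are available (deficit %d)",
      m, n, m - n
    ))
  }
  src <- matches$points_src
  dst <- matches$points_dst
  best_inl <- logical(n)
  best_count <- -1L
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      pick <- sample.int(n, m)
      t <- tryCatch(
        fit_constrained_transform(subset_matches(matches, pick), spec),
        error = function(e) NULL
      )
      if (is.null(t)) next
      res <- transform_points(t, src) - dst
      inl <- sqrt(rowSums(res^2)) < inlier_tol_px
      cnt <- sum(inl)
      if (cnt > best_count) {
        best_count <- cnt
        best_inl <- inl
      }
    }
  })
  if (best_count <= 0L) {
    stop("RANSAC found no consensus set (all sample fits failed or no inliers)")
  }
  out <- subset_matches(matches, best_inl)
  attr(out, "n_inliers") <- best_count
  out
}
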