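#' Align a serial FIB/SEM stack with a constrained transformation family
#'
#' Starting from the first slice (the reference), landmarks are detected
#' and matched between every consecutive pair, outliers are removed with
#' the chosen filter, and the best transform of the constrained family is
#' fitted by least squares.  Pairwise transforms map each slice into its
#' predecessor's frame; their running composition maps every slice into the
#' reference frame, and each slice is resampled exactly once through its
#' cumulative transform (no repeated interpolation), with out-of-frame
#' pixels filled by the slice median.
#'
#' Pairs with too few matches fall back to the previous pairwise transform
#' (or the identity for the first pair) and are flagged; degradation is
#' reported in the result, never raised.
#'
#' @param stack an [image_stack] with at least 2 slices.
#' @param spec a [transform_spec]; the recommended configuration for
#'   FIB/SEM is `{translate, shear_x, stretch_y}`, which makes a fitted
#'   rotation structurally impossible.
#' @param filter outlier filter: `list(type = "ransac", inlier_tol_px = 2,
#'   n_iter = 1000, seed = 0)` or `list(type = "percentile", q = 5)`.
#' @param detector a [detector_params].
#' @param interpolation resampling scheme for the output stack.
#' @return list with `stack` (the aligned [image_stack]) and `result`, an
#'   `alignment_result` carrying `pairwise` (length `n - 1`, slice `k+1` ->
#'   slice `k` frame), `cumulative` (length `n`, first = identity),
#'   `n_matches_used`, `residual_rms` (px), `fallback` flags, and the spec /
#'   filter / detector settings used.
#' @export
align_stack <- function(stack, spec,
                        filter = list(type = "ransac", inlier_tol_px = 2,
                                      n_iter = 1000L, seed = 0L),
                        detector = detector_params(),
                        interpolation = "bilinear") {
  stopifnot(inherits(stack, "image_stack"), inherits(spec, "transform_spec"))
  n <- stack$n_slices
  if (n < 2L) stop("need at least 2 slices to align")
  min_needed <- max(3L, ceiling(spec_n_params(spec) / 2))
  pairwise <- vector("list", n - 1L)
  n_used <- integer(n - 1L)
  rms <- rep(NA_real_, n - 1L)
  fallback <- logical(n - 1L)
  for (k in seq_len(n - 1L)) {
    # src = slice k+1, dst = slice k: the fitted map takes slice k+1
    # coordinates into slice k's frame
    m <- detect_and_match(get_slice(stack, k + 1L), get_slice(stack, k),
                          params = detector)
    t <- NULL
    if (n_matches(m) >= min_needed) {
      mf <- tryCatch(
        switch(filter$type,
          ransac = filter_matches_ransac(
            m, spec,
            inlier_tol_px = filter$inlier_tol_px %||% 2,
            n_iter = filter$n_iter %||% 1000L,
            seed = filter$seed %||% 0L
          ),
          percentile = filter_matches_percentile(m, q = filter$q %||% 5),
          stop(sprintf("unknown filter type '%s'", filter$type))
        ),
        error = function(e) NULL
      )
      if (!is.null(mf) && n_matches(mf) >= min_needed) {
        t <- tryCatch(fit_constrained_transform(mf, spec),
                      error = function(e) NULL)
        if (!is.null(t)) {
          n_used[k] <- n_matches(mf)
          rms[k] <- attr(t, "residual_rms")
        }
      }
    }
    if (is.null(t)) {
      t <- if (k > 1L) pairwise[[k - 1L]] else identity_transform()
      fallback[k] <- TRUE
      n_used[k] <- 0L
    }
    pairwise[[k]] <- t
  }
  cumulative <- compose_transforms(pairwise)
  out <- stack$data
  for (k in 2:n) {
    out[k, , ] <- apply_transform(get_slice(stack, k), cumulative[[k]],
                                  interpolation = interpolation)
  }
  result <- structure(
    list(pairwise = pairwise, cumulative = cumulative,
         n_matches_used = n_used, residual_rms = rms, fallback = fallback,
         spec = spec, filter = filter, detector = detector),
    class = "alignment_result"
  )
  list(stack = image_stack(out, pixel_size_nm = stack$pixel_size_nm),
       result = result)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> %d pairs: median matches %s, median residual %.3f px, %d fallback(s)\n",
    length(x$pairwise), median(x$n_matches_used),
    median(x$residual_rms, na.rm = TRUE), sum(x$fallback)
  ))
  invisible(x)
}

# Serializes an alignment result to a JSON-ready list (used by the CLI).
alignment_result_to_list <- function(res) {
  spec_flags <- names(Filter(isTRUE, unclass(res$spec)))
  list(
    spec = spec_flags,
    filter = res$filter,
    detector = unclass(res$detector),
    slices = lapply(seq_along(res$cumulative), function(k) {
      t <- res$cumulative[[k]]
      list(
        slice = k - 1L,
        A = list(t$A[1, ], t$A[2, ]),
        b = t$b,
        residual_rms = if (k > 1L) res$residual_rms[k - 1L] else 0,
        n_matches = if (k > 1L) res$n_matches_used[k - 1L] else NA,
        fallback = if (k > 1L) res$fallback[k - 1L] else FALSE
      )
    })
  )
}
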