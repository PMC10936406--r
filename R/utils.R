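#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the global RNG seed for the duration of `code` and restores the
#' previous RNG state on exit, so seeded operations (generators, RANSAC)
#' never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Symmetric Hann window of length n (n = 1 gives 1).
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# Gaussian blur of a plain matrix (EBImage::gblur, coerced back to matrix).
gblur_mat <- function(m, sigma) {
  out <- EBImage::imageData(EBImage::gblur(m, sigma = sigma))
  matrix(as.numeric(out), nrow(m), ncol(m))
}

# Checks a matrix is a finite numeric 2D image.
check_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(img)
}
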