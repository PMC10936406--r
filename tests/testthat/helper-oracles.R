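# Independent oracles and shared fixtures, kept deliberately naive: the
# point is that they compute the same quantities by a different route than
# the package (explicit loops, closed forms), never by calling the code
# under test.

# Brute-force FRC: explicit double loop over every DFT bin, accumulating
# per-ring sums with the same ring rule (ring = round(radius), rings
# 1..n/2) but none of the package's vectorized machinery.
frc_brute_force <- function(img1, img2, window = c("hann", "none")) {
  window <- match.arg(window)
  n <- nrow(img1)
  if (window == "hann") {
    h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    w <- outer(h, h)
    img1 <- img1 * w
    img2 <- img2 * w
  }
  F1 <- stats::fft(img1)
  F2 <- stats::fft(img2)
  nyq <- n %/% 2
  num <- numeric(nyq)
  p1 <- numeric(nyq)
  p2 <- numeric(nyq)
  for (i in 1:n) {
    for (j in 1:n) {
      fy <- if (i - 1 <= n / 2) i - 1 else i - 1 - n
      fx <- if (j - 1 <= n / 2) j - 1 else j - 1 - n
      q <- round(sqrt(fx^2 + fy^2))
      if (q < 1 || q > nyq) next
      num[q] <- num[q] + Re(F1[i, j] * Conj(F2[i, j]))
      p1[q] <- p1[q] + Mod(F1[i, j])^2
      p2[q] <- p2[q] + Mod(F2[i, j])^2
    }
  }
  list(freq = (1:nyq) / nyq, corr = num / sqrt(p1 * p2))
}

# Manual percentile bound (the standard linear-interpolation definition on
# the order statistics), written out longhand.
manual_percentile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Random match set drawn from a known transform plus optional noise.
random_match_set <- function(n, A = diag(2), b = c(0, 0), noise = 0,
                             seed = 1, extent = 200) {
  set.seed(seed)
  src <- cbind(runif(n, 0, extent), runif(n, 0, extent))
  dst <- sweep(src %*% t(A), 2, b, "+")
  if (noise > 0) dst <- dst + matrix(rnorm(2 * n, sd = noise), n, 2)
  match_set(src, dst)
}

# Hand-constructed FRC curve object for crossing-rule tests.
fake_frc_curve <- function(freq, corr) {
  structure(list(freq = freq, corr = corr, n_bins = rep(1L, length(freq)),
                 n_px = 2L * length(freq), window = "none"),
            class = "frc_curve")
}

# The elongated-droplet charging fixture used across chafer tests: one
# asymmetric charging centre in a wide short field, with an artifact-to-
# noise ratio emulating strong real-world charging.
charging_fixture <- function(seed = 0, noise_sigma = 2) {
  make_charging_image(
    shape = c(128, 256),
    centers = data.frame(x = 128, y = 64, rx = 60, ry = 12),
    tail_params = list(list(left = c(-40, 20), right = c(-50, 30))),
    background_level = 100, center_depth = -50,
    noise_sigma = noise_sigma, seed = seed
  )
}

# Float32-exact random values (integers plus halves), so preserve-float32
# round trips can be compared bitwise.
f32_exact_array <- function(dim, seed = 1) {
  set.seed(seed)
  array(sample(seq(-100, 155, by = 0.5), prod(dim), replace = TRUE), dim = dim)
}
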