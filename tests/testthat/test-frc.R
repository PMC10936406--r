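test_that("FRC closed forms: self-correlation 1, sign flip -1, symmetry", {
  img <- make_textured_image(c(64, 64), seed = 1)
  c_self <- compute_frc(img, img)
  expect_true(all(abs(c_self$corr - 1) < 1e-9))
  c_neg <- compute_frc(img, -img)
  expect_true(all(abs(c_neg$corr + 1) < 1e-9))
  img2 <- make_textured_image(c(64, 64), seed = 2)
  a <- compute_frc(img, img2)
  b <- compute_frc(img2, img)
  expect_lt(max(abs(a$corr - b$corr)), 1e-12)
  expect_true(all(diff(a$freq) > 0))
  expect_equal(a$freq[length(a$freq)], 1)
  expect_error(compute_frc(matrix(0, 16, 16), img[1:16, 1:16]), "all-zero")
})

test_that("ring summation equals brute-force enumeration over all DFT bins", {
  set.seed(3)
  a <- matrix(rnorm(64 * 64), 64, 64)
  b <- 0.6 * a + 0.4 * matrix(rnorm(64 * 64), 64, 64)
  for (win in c("hann", "none")) {
    got <- compute_frc(a, b, window = win)
    want <- frc_brute_force(a, b, window = win)
    expect_equal(got$freq, want$freq)
    expect_equal(got$corr, want$corr, tolerance = 1e-12)
  }
})

test_that("white-noise images decorrelate at the expected ring level", {
  set.seed(4)
  a <- matrix(rnorm(64 * 64), 64, 64)
  b <- matrix(rnorm(64 * 64), 64, 64)
  curve <- compute_frc(a, b, window = "none")
  bound <- 3 / sqrt(curve$n_bins)
  expect_gte(mean(abs(curve$corr) < bound), 0.95)
})

test_that("threshold crossing uses linear interpolation with the 2px convention", {
  freq <- seq(0.05, 1, by = 0.05)
  lin <- fake_frc_curve(freq, 1 - freq)
  r <- resolution_from_curve(lin, threshold = 1 / 7)
  expect_equal(r$f_crossing, 6 / 7, tolerance = 1e-12)
  expect_equal(r$resolution_px, 2 / (6 / 7), tolerance = 1e-12)
  expect_equal(r$resolution_px, 2.3333, tolerance = 1e-4)
  expect_equal(r$status, "ok")

  const <- fake_frc_curve(freq, rep(0.9, length(freq)))
  r2 <- resolution_from_curve(const)
  expect_equal(r2$status, "at-limit")
  expect_equal(r2$f_crossing, 1)
  expect_equal(r2$resolution_px, 2)

  dead <- fake_frc_curve(freq, rep(0.01, length(freq)))
  r3 <- resolution_from_curve(dead)
  expect_equal(r3$status, "unresolved")
  expect_equal(r3$f_crossing, freq[1])

  # physical scaling: halving the pixel size halves the physical resolution
  ra <- resolution_from_curve(lin, pixel_size_nm = 4)
  rb <- resolution_from_curve(lin, pixel_size_nm = 2)
  expect_equal(ra$resolution_nm / 2, rb$resolution_nm)
})

test_that("checkerboard split partitions pixels by parity", {
  m2 <- matrix(1:4, 2, 2) # rows: [1, 3] / [2, 4]
  s <- checkerboard_split(m2 * 1.0)
  expect_equal(s$sub_ee, matrix(1, 1, 1))   # row 0, col 0
  expect_equal(s$sub_oo, matrix(4, 1, 1))   # row 1, col 1
  expect_equal(s$sub_eo, matrix(3, 1, 1))   # row 0, col 1
  expect_equal(s$sub_oe, matrix(2, 1, 1))   # row 1, col 0

  img <- matrix(rnorm(13 * 17), 13, 17) # odd dims are cropped by one
  s2 <- checkerboard_split(img)
  n_total <- sum(vapply(s2, length, numeric(1)))
  expect_equal(n_total, 12 * 16)
  expect_equal(sort(unname(unlist(lapply(s2, as.vector)))),
               sort(as.vector(img[1:12, 1:16])))

  const <- matrix(5, 8, 8)
  s3 <- checkerboard_split(const)
  expect_true(all(vapply(s3, function(x) all(x == 5), logical(1))))
  expect_error(checkerboard_split(matrix(1, 1, 3)), "2x2")
})

test_that("one-image FRC is deterministic and honours an identity calibration", {
  p <- make_bandlimited_pair(c(256, 256), cutoff_norm = 0.5, snr = 5, seed = 7)
  r1 <- one_image_frc(p$img_a)
  r2 <- one_image_frc(p$img_a)
  expect_identical(r1$resolution_px, r2$resolution_px)
  rc <- one_image_frc(p$img_a, calibration = identity_calibration())
  expect_equal(rc$resolution_px, r1$resolution_px)
  expect_true(rc$calibrated)
  expect_false(r1$calibrated)
})

test_that("uncalibrated one-image resolution is one-sidedly finer than the two-image oracle", {
  for (seed in c(0, 8, 15)) {
    p <- make_bandlimited_pair(c(256, 256), cutoff_norm = 0.5, snr = 5, seed = seed)
    d2 <- resolution_from_curve(compute_frc(p$img_a, p$img_b))$resolution_px
    d1 <- one_image_frc(p$img_a)$resolution_px
    expect_lt(d1, d2)
  }
})

test_that("power-law calibration fitting recovers known coefficients", {
  d1 <- c(2, 3, 4.5, 6, 8)
  ident <- fit_calibration_points(d1, d1)
  expect_equal(ident$alpha, 1, tolerance = 1e-9)
  expect_equal(ident$beta, 1, tolerance = 1e-9)

  set.seed(9)
  d1 <- runif(12, 2, 10)
  d2 <- 1.3 * d1^0.9 * exp(rnorm(12, sd = 0.01))
  cal <- fit_calibration_points(d1, d2)
  expect_equal(cal$alpha, 1.3, tolerance = 0.05 * 1.3)
  expect_equal(cal$beta, 0.9, tolerance = 0.05 * 0.9)
  expect_equal(cal$domain, range(d1))
  expect_true(cal$monotone)
  pred <- predict_calibration(cal, c(1, 5))
  expect_true(pred$outside_domain[1])
  expect_false(pred$outside_domain[2])
})

test_that("image-level calibration accepts three pixel sizes with a pair each", {
  pairs <- lapply(seq_along(c(1.12, 2.25, 4.5)), function(i) {
    px <- c(1.12, 2.25, 4.5)[i]
    cutoff <- c(0.8, 0.5, 0.3)[i] # resolution varies across magnifications
    p <- make_bandlimited_pair(c(128, 128), cutoff_norm = cutoff, snr = 4,
                               seed = 30 + i)
    list(img_a = p$img_a, img_b = p$img_b, pixel_size_nm = px)
  })
  cal <- fit_calibration(pairs)
  expect_s3_class(cal, "calibration_model")
  expect_equal(cal$provenance$n_pairs, 3)
  expect_equal(cal$provenance$pixel_sizes_nm, c(1.12, 2.25, 4.5))
  expect_true(all(is.finite(c(cal$alpha, cal$beta))))
  expect_error(fit_calibration(pairs[1]), "at least 2")
})

test_that("tiled resolution is homogeneous on a homogeneous image and masks exclude tiles", {
  p <- make_bandlimited_pair(c(512, 512), cutoff_norm = 0.5, snr = 5, seed = 11)
  whole <- one_image_frc(p$img_a)$resolution_px
  map <- tiled_resolution(p$img_a, 128)
  expect_equal(map$summary$n_tiles, 16)
  expect_lt(abs(map$summary$median_px - whole) / whole, 0.10)

  mask <- matrix(0L, 512, 512)
  mask[, 1:256] <- 1L
  map2 <- tiled_resolution(p$img_a, 128, mask = mask)
  expect_equal(map2$summary$n_tiles, 8)
  expect_true(all(map2$tiles$included[map2$tiles$x0 >= 256]))
  expect_true(all(!map2$tiles$included[map2$tiles$x0 < 256]))

  expect_error(tiled_resolution(p$img_a, 1024), "exceeds")
  expect_error(tiled_resolution(p$img_a, 16), ">= 32")
})

test_that("tile-size report: identical groups give p ~ 1, distinct groups reject", {
  v <- c(2.1, 2.2, 2.15, 2.05, 2.3, 2.12, 2.18, 2.25)
  rep_null <- fibsemtools:::tile_size_report(list(a = v, b = v, c = v))
  expect_gt(rep_null$p_value, 0.99)
  expect_equal(rep_null$max_median_diff_px, 0)

  set.seed(13)
  g1 <- rnorm(40, 2.1, 0.05)
  g2 <- rnorm(40, 3.0, 0.05)
  rep_alt <- fibsemtools:::tile_size_report(list(a = g1, b = g2))
  expect_lt(rep_alt$p_value, 0.01)
})
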