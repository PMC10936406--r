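test_that("row segments are maximal runs of nonzero mask pixels", {
  mask <- matrix(0L, 2, 10)
  mask[1, ] <- c(0, 0, 0, 1, 1, 1, 0, 0, 1, 0)
  segs <- extract_row_segments(mask, 1)
  expect_equal(segs$x_start, c(3, 8))
  expect_equal(segs$x_end, c(5, 8))
  expect_equal(nrow(extract_row_segments(mask, 2)), 0)
  mask[2, ] <- 1L
  expect_equal(extract_row_segments(mask, 2), data.frame(x_start = 0L, x_end = 9L))
})

test_that("row background averages preceding rows with column-wise mask exclusion", {
  img <- matrix(100, 6, 8)
  mask <- matrix(0L, 6, 8)
  expect_equal(estimate_row_background(img, mask, 4, 3, "down"), rep(100, 8))

  img[1, ] <- 10; img[2, ] <- 20; img[3, ] <- 30
  expect_equal(estimate_row_background(img, mask, 4, 3, "down"), rep(20, 8))

  mask[2, 6] <- 1L # 0-based column 5
  bg <- estimate_row_background(img, mask, 4, 3, "down")
  expect_equal(bg[6], 20) # mean of 10 and 30
  expect_equal(bg[1], 20)

  # distinguishable exclusion case
  img[3, ] <- 40
  bg2 <- estimate_row_background(img, mask, 4, 3, "down")
  expect_equal(bg2[6], 25)       # (10 + 40) / 2
  expect_equal(bg2[1], 70 / 3)   # (10 + 20 + 40) / 3

  # up pass uses the rows below
  img[5, ] <- 7; img[6, ] <- 9
  expect_equal(estimate_row_background(img, mask, 4, 2, "up"), rep(8, 8))
  expect_error(estimate_row_background(img, mask, 1, 3, "down"), "preceding")
})

test_that("sigmoid tail evaluates to the closed form with the stated side convention", {
  left <- sigmoid_tail_model("left", amplitude = -30, center = 40, width = 5)
  expect_equal(sigmoid_tail(40, left), -15)                      # midpoint a/2
  expect_equal(sigmoid_tail(50, left), -30 / (1 + exp(-2)))      # ~ -26.43
  expect_equal(sigmoid_tail(-1e6, left), 0, tolerance = 1e-12)   # away -> 0
  expect_equal(sigmoid_tail(1e6, left), -30)                     # toward segment
  right <- sigmoid_tail_model("right", amplitude = 12, center = 80, width = 4)
  expect_equal(sigmoid_tail(1e6, right), 0, tolerance = 1e-12)
  expect_equal(sigmoid_tail(-1e6, right), 12)
  expect_error(sigmoid_tail_model("left", -5, 10, width = 0), "positive")
})

test_that("noiseless synthetic tails are recovered to 1e-3 per parameter", {
  gen <- make_charging_image(
    shape = c(64, 128), centers = data.frame(x = 64, y = 32, rx = 20, ry = 6),
    tail_params = list(list(left = c(-25, 6), right = c(-30, 9))),
    background_level = 100, noise_sigma = 0, seed = 1
  )
  row <- 33 # crosses the ellipse's widest chord
  segs <- extract_row_segments(gen$mask, row)
  diff <- gen$image[row, ] - 100
  diff[gen$mask[row, ] != 0] <- NA
  f <- fit_tail_sigmoids(diff, segs, 1)
  expect_equal(f$left$amplitude, -25, tolerance = 1e-3)
  expect_equal(f$left$center, segs$x_start[1], tolerance = 1e-3)
  expect_equal(f$left$width, 6, tolerance = 1e-3)
  expect_equal(f$right$amplitude, -30, tolerance = 1e-3)
  expect_equal(f$right$center, segs$x_end[1], tolerance = 1e-3)
  expect_equal(f$right$width, 9, tolerance = 1e-3)
})

test_that("a zero difference signal fits a near-zero amplitude (no-op subtraction)", {
  segs <- data.frame(x_start = 40L, x_end = 60L)
  diff <- rep(0, 128)
  f <- fit_tail_sigmoids(diff, segs, 1)
  expect_false(is.null(f$left))
  expect_lt(abs(f$left$amplitude), 1e-6)
  expect_lt(abs(f$right$amplitude), 1e-6)
  row <- rep(100, 128)
  out <- correct_row(row, segs, list(f))
  expect_equal(out, row, tolerance = 1e-6)
})

test_that("amplitude recovery under 5% noise is within 10% (median over seeds)", {
  # tail half-point 20 px outside the labelled segment, so the window sees
  # the full S-curve including its saturated plateau
  segs <- data.frame(x_start = 90L, x_end = 110L)
  amp <- -30; wid <- 8
  true_left <- sigmoid_tail_model("left", amp, 70, wid)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    diff <- rep(0, 140)
    diff[1:90] <- sigmoid_tail(0:89, true_left)
    diff <- diff + rnorm(140, sd = 0.05 * abs(amp))
    diff[91:111] <- NA
    f <- fit_tail_sigmoids(diff, segs, 1)
    if (is.null(f$left)) return(NA_real_)
    abs(f$left$amplitude - amp) / abs(amp)
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("short or absent windows fail soft (NULL side), never raise", {
  segs <- data.frame(x_start = 1L, x_end = 120L)
  diff <- rep(0, 128)
  f <- fit_tail_sigmoids(diff, segs, 1)
  expect_null(f$left)   # only 1 pixel to the left
  expect_false(is.null(f$right))
})

test_that("correct_row subtracts fitted tails outside the mask only", {
  nx <- 128
  segs <- data.frame(x_start = 50L, x_end = 70L)
  left <- sigmoid_tail_model("left", -20, 50, 7)
  right <- sigmoid_tail_model("right", -28, 70, 10)
  row <- rep(100, nx)
  row[1:50] <- row[1:50] + sigmoid_tail(0:49, left)
  row[72:nx] <- row[72:nx] + sigmoid_tail(71:(nx - 1), right)
  row[51:71] <- 55 # the charging centre itself
  mask_row <- rep(0L, nx); mask_row[51:71] <- 1L
  out <- correct_row(row, segs, list(list(left = left, right = right)),
                     mask_row = mask_row)
  expect_equal(out[c(1:50, 72:nx)], rep(100, nx - 21), tolerance = 0.5)
  expect_identical(out[51:71], row[51:71])
  # no segments, or all-NULL fits: identity
  expect_identical(correct_row(row, segs[0, ], list()), row)
  expect_identical(correct_row(row, segs, list(list(left = NULL, right = NULL))), row)
})

test_that("chafer filter is a bitwise no-op on an empty mask and is deterministic", {
  gen <- charging_fixture(seed = 3)
  empty <- matrix(0L, nrow(gen$image), ncol(gen$image))
  out <- chafer_filter(gen$image, empty)
  expect_identical(as.vector(out), as.vector(gen$image))

  f1 <- chafer_filter(gen$image, gen$mask)
  f2 <- chafer_filter(gen$image, gen$mask)
  expect_identical(as.vector(f1), as.vector(f2))
  expect_error(chafer_filter(gen$image, matrix(0L, 4, 4)), "mask shape")
})

test_that("chafer strongly reduces background spread near the centre, leaves the mask alone", {
  gen <- charging_fixture(seed = 0)
  filt <- chafer_filter(gen$image, gen$mask)
  rep <- background_std_report(gen$image, filt, gen$mask, radius_px = 50)
  expect_gte(rep$percent_reduction, 50)
  expect_lt(rep$std_after, rep$std_before) # strict improvement
  # masked pixels untouched: mean change far below 1% of dynamic range
  dyn <- diff(range(gen$image))
  expect_lt(abs(mean(filt[gen$mask != 0]) - mean(gen$image[gen$mask != 0])),
            0.01 * dyn)
  expect_identical(filt[gen$mask != 0], gen$image[gen$mask != 0])
})

test_that("background std report matches an independent recomputation", {
  gen <- charging_fixture(seed = 5)
  filt <- chafer_filter(gen$image, gen$mask)
  radius <- 30
  rep <- background_std_report(gen$image, filt, gen$mask, radius_px = radius)

  # independent recomputation: explicit Chebyshev distance scan
  lab <- which(gen$mask != 0, arr.ind = TRUE)
  ny <- nrow(gen$image); nx <- ncol(gen$image)
  near <- matrix(FALSE, ny, nx)
  for (k in seq_len(nrow(lab))) {
    r0 <- max(1, lab[k, 1] - radius):min(ny, lab[k, 1] + radius)
    c0 <- max(1, lab[k, 2] - radius):min(nx, lab[k, 2] + radius)
    near[r0, c0] <- TRUE
  }
  region <- near & gen$mask == 0
  expect_equal(rep$std_before, sd(gen$image[region]))
  expect_equal(rep$std_after, sd(filt[region]))
  expect_equal(rep$percent_reduction,
               100 * (1 - sd(filt[region]) / sd(gen$image[region])))

  # degenerate contracts
  expect_equal(background_std_report(gen$image, gen$image, gen$mask)$percent_reduction, 0)
  flat <- gen$image; flat[region] <- mean(gen$image[region])
  expect_equal(background_std_report(gen$image, flat, gen$mask,
                                     radius_px = radius)$percent_reduction,
               100)
  expect_error(background_std_report(gen$image, filt, matrix(0L, ny, nx)),
               "no labelled")
})
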