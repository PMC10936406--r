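test_that("spec validation rejects unsupported flag mixes", {
  expect_error(transform_spec(rotate = TRUE, shear_x = TRUE), "rotate")
  expect_error(transform_spec(scale_uniform = TRUE, stretch_y = TRUE),
               "scale_uniform")
  # affine overrides everything else
  sp <- transform_spec(affine = TRUE, rotate = TRUE)
  expect_true(sp$affine)
  expect_false(sp$rotate)
  expect_identical(parse_transform_spec("translate,shear_x")$shear_x, TRUE)
  expect_error(parse_transform_spec("translate,wobble"), "wobble")
})

test_that("identity correspondences give the exact identity for any family", {
  m <- random_match_set(20, seed = 3)
  m <- match_set(m$points_src, m$points_src)
  for (sp in list(
    transform_spec(translate = TRUE, shear_x = TRUE),
    transform_spec(translate = TRUE, shear_x = TRUE, stretch_y = TRUE),
    transform_spec(translate = TRUE, rotate = TRUE),
    transform_spec(affine = TRUE)
  )) {
    t <- fit_constrained_transform(m, sp)
    expect_equal(t$A, diag(2), tolerance = 1e-12)
    expect_equal(t$b, c(0, 0), tolerance = 1e-12)
  }
})

test_that("a pure x-shear of 0.15 is recovered exactly with disabled entries at identity", {
  A <- matrix(c(1, 0, 0.15, 1), 2, 2)
  m <- random_match_set(30, A = A, seed = 5)
  t <- fit_constrained_transform(m, transform_spec(translate = TRUE, shear_x = TRUE))
  expect_equal(t$A[1, 2], 0.15, tolerance = 1e-9)
  expect_identical(t$A[1, 1], 1)
  expect_identical(t$A[2, 2], 1)
  expect_identical(t$A[2, 1], 0)
})

test_that("linear families are solved to least-squares optimality (generic-affine oracle)", {
  A <- matrix(c(1.1, 0, 0.05, 0.9), 2, 2)
  b <- c(4, -2)
  m <- random_match_set(6, A = A, b = b, seed = 7)
  sp <- transform_spec(translate = TRUE, shear_x = TRUE,
                       stretch_x = TRUE, stretch_y = TRUE)
  t <- fit_constrained_transform(m, sp)
  expect_equal(t$A, A, tolerance = 1e-9)
  expect_equal(t$b, b, tolerance = 1e-9)
  expect_identical(t$A[2, 1], 0)

  # oracle: unconstrained least squares via lm on the same correspondences
  # recovers the same entries, since the truth lies inside the family
  src <- m$points_src; dst <- m$points_dst
  fx <- lm(dst[, 1] ~ src[, 1] + src[, 2])
  fy <- lm(dst[, 2] ~ src[, 1] + src[, 2])
  expect_equal(unname(coef(fx)), c(b[1], A[1, 1], A[1, 2]), tolerance = 1e-9)
  expect_equal(unname(coef(fy)), c(b[2], A[2, 1], A[2, 2]), tolerance = 1e-9)
})

test_that("rotation families use the closed-form Procrustes solution", {
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  m <- random_match_set(25, A = R, b = c(3, 8), seed = 11)
  t <- fit_constrained_transform(m, transform_spec(translate = TRUE, rotate = TRUE))
  expect_equal(t$A, R, tolerance = 1e-9)
  expect_equal(t$b, c(3, 8), tolerance = 1e-9)

  m2 <- random_match_set(25, A = 1.2 * R, b = c(-5, 1), seed = 12)
  t2 <- fit_constrained_transform(
    m2, transform_spec(translate = TRUE, rotate = TRUE, scale_uniform = TRUE)
  )
  expect_equal(t2$A, 1.2 * R, tolerance = 1e-9)
  expect_equal(t2$b, c(-5, 1), tolerance = 1e-9)
})

test_that("constraint exactness holds on noisy random match sets", {
  sp <- transform_spec(translate = TRUE, shear_x = TRUE, stretch_y = TRUE)
  for (i in 1:100) {
    A <- matrix(c(1, 0, runif(1, -0.3, 0.3), runif(1, 0.8, 1.2)), 2, 2)
    m <- random_match_set(12, A = A, b = runif(2, -20, 20), noise = 1.5,
                          seed = i)
    t <- fit_constrained_transform(m, sp)
    expect_identical(t$A[2, 1], 0)
    expect_identical(t$A[1, 1], 1)
  }
})

test_that("degenerate fits raise: too few matches, collinear points for affine", {
  m <- random_match_set(2, seed = 1)
  expect_error(fit_constrained_transform(m, transform_spec(affine = TRUE)),
               "at least 3")
  src <- cbind(1:5, 2 * (1:5)) # collinear
  expect_error(
    fit_constrained_transform(match_set(src, src + 1), transform_spec(affine = TRUE)),
    "rank-deficient|collinear"
  )
})

test_that("composition matches explicit matrix products and is additive for shears", {
  t1 <- affine2d(diag(2), c(1, 0))
  t2 <- affine2d(diag(2), c(0, 2))
  cum <- compose_transforms(list(t1, t2))
  expect_equal(cum[[1]]$A, diag(2))
  expect_equal(cum[[1]]$b, c(0, 0))
  expect_equal(cum[[3]]$b, c(1, 2))

  s1 <- affine2d(matrix(c(1, 0, 0.1, 1), 2, 2))
  s2 <- affine2d(matrix(c(1, 0, 0.2, 1), 2, 2))
  expect_equal(compose_transforms(list(s1, s2))[[3]]$A[1, 2], 0.3)

  # associativity oracle: cumulative equals one-shot products
  set.seed(42)
  pw <- lapply(1:5, function(i) {
    affine2d(diag(2) + matrix(rnorm(4, sd = 0.05), 2, 2), rnorm(2))
  })
  cum <- compose_transforms(pw)
  Acc <- diag(2); bcc <- c(0, 0)
  for (k in 1:5) {
    Acc2 <- Acc %*% pw[[k]]$A
    bcc <- as.numeric(Acc %*% pw[[k]]$b) + bcc
    Acc <- Acc2
    expect_equal(cum[[k + 1]]$A, Acc, tolerance = 1e-14)
    expect_equal(cum[[k + 1]]$b, bcc, tolerance = 1e-14)
  }
})

test_that("apply_transform: identity, integer shifts and near-inverse round trip", {
  img <- make_textured_image(c(64, 64), seed = 2)
  expect_identical(apply_transform(img, identity_transform()), img)

  t3 <- affine2d(diag(2), c(3, 0))
  sh <- apply_transform(img, t3, interpolation = "nearest", fill_value = -7)
  expect_equal(sh[, 4:64], img[, 1:61])
  expect_true(all(sh[, 1:3] == -7))

  smooth <- make_textured_image(c(64, 64), blob_sigma = 5, noise_sigma = 0,
                                seed = 2)
  t <- affine2d(matrix(c(1, 0, 0.08, 1), 2, 2), c(2.5, -1.5))
  round_trip <- apply_transform(apply_transform(smooth, t), invert_transform(t))
  # interior excludes the border reached by the translation plus the shear
  # sweep (|b| + 0.08 * height + 2)
  interior <- 12:52
  dyn <- diff(range(smooth))
  expect_lt(max(abs(round_trip[interior, interior] - smooth[interior, interior])),
            0.01 * dyn)

  expect_error(apply_transform(img, affine2d(matrix(0, 2, 2))), "singular")
})
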