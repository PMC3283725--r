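test_that("rigid transform algebra: compose, invert, apply", {
  a <- rigid_transform(3.2, -1.7, 0.8)
  b <- rigid_transform(-0.5, 2.1, -0.3)
  dims <- c(200L, 150L)
  x <- c(10, 75.5, 149); y <- c(10, 100.25, 199)

  # compose(a, b) applied = b(a(.))
  pa <- rt_apply(a, x, y, dims)
  pab <- rt_apply(b, pa$x_px, pa$y_px, dims)
  pc <- rt_apply(rt_compose(a, b), x, y, dims)
  expect_equal(pab$x_px, pc$x_px, tolerance = 1e-9)
  expect_equal(pab$y_px, pc$y_px, tolerance = 1e-9)

  # invert is the exact inverse
  inv <- rt_invert(a)
  back <- rt_apply(inv, pa$x_px, pa$y_px, dims)
  expect_equal(back$x_px, x, tolerance = 1e-9)
  expect_equal(back$y_px, y, tolerance = 1e-9)
  id <- rt_compose(a, inv)
  expect_equal(c(id$dx_px, id$dy_px, id$theta_deg), c(0, 0, 0),
               tolerance = 1e-12)

  # pure translation moves points by exactly (dx, dy)
  t <- rigid_transform(4, -7, 0)
  pt <- rt_apply(t, x, y, dims)
  expect_equal(pt$x_px, x + 4)
  expect_equal(pt$y_px, y - 7)
})

test_that("warping by an integer translation shifts pixels exactly", {
  m <- matrix(0, 40, 40)
  m[20, 15] <- 1
  w <- warp_rigid(m, rigid_transform(5, -3, 0))
  expect_equal(w[17, 20], 1)
  expect_equal(sum(w), 1)
  # out-of-field content filled with 0 for matrices
  expect_equal(sum(warp_rigid(m, rigid_transform(39, 0, 0))), 0)
})

test_that("warp round trip through a subpixel rigid transform is near-lossless", {
  set.seed(7)
  base <- matrix(0, 120, 120)
  for (k in 1:15) {
    cx <- runif(1, 30, 90); cy <- runif(1, 30, 90)
    d2 <- outer((1:120 - cy)^2, (1:120 - cx)^2, `+`)
    base <- base + exp(-d2 / (2 * 4^2))
  }
  base <- base / max(base)
  t <- rigid_transform(2.3, -1.6, 0.7)
  back <- warp_rigid(warp_rigid(base, t), rt_invert(t))
  inner <- 15:106
  expect_lt(mean(abs(back[inner, inner] - base[inner, inner])), 0.01)
})

test_that("phase correlation recovers planted transforms", {
  set.seed(42)
  n <- 256L
  truth_field <- matrix(0, n, n)
  for (k in 1:40) {
    cx <- runif(1, 20, n - 20); cy <- runif(1, 20, n - 20)
    d2 <- outer((1:n - cy)^2, (1:n - cx)^2, `+`)
    truth_field <- truth_field + exp(-d2 / (2 * 3^2))
  }
  truth_field <- clip01(truth_field / max(truth_field))

  # identity
  t0 <- estimate_rigid(truth_field, truth_field)
  expect_lt(abs(t0$dx_px), 0.05)
  expect_lt(abs(t0$dy_px), 0.05)
  expect_lt(abs(t0$theta_deg), 0.05)

  # integer shift, no rotation
  t_int <- rigid_transform(7, -4, 0)
  mov <- warp_rigid(truth_field, t_int)
  est <- estimate_rigid(truth_field, mov)
  expect_equal(est$dx_px, 7, tolerance = 0.1)
  expect_equal(est$dy_px, -4, tolerance = 0.1)
  expect_lt(abs(est$theta_deg), 0.05)

  # subpixel shift + rotation: rotation needs the full working field size
  # (the angular lever arm scales with the field), so test at 512 px
  set.seed(43)
  n2 <- 512L
  big <- matrix(0, n2, n2)
  for (k in 1:120) {
    cx <- runif(1, 20, n2 - 20); cy <- runif(1, 20, n2 - 20)
    d2 <- outer((1:n2 - cy)^2, (1:n2 - cx)^2, `+`)
    big <- big + exp(-d2 / (2 * 3^2))
  }
  big <- clip01(big / max(big))
  t_sub <- rigid_transform(3.5, -2.25, 0.5)
  mov2 <- warp_rigid(big, t_sub)
  est2 <- estimate_rigid(big, mov2)
  expect_lt(abs(est2$dx_px - 3.5), 0.5)
  expect_lt(abs(est2$dy_px + 2.25), 0.5)
  # an isolated-dot field is the hardest texture for the rotation search;
  # rendered slide maps do noticeably better (see the end-to-end tests)
  expect_lt(abs(est2$theta_deg - 0.5), 0.15)

  # alignment semantics: warping the moving image by the inverse estimate
  # restores the reference
  aligned <- warp_rigid(mov2, rt_invert(est2))
  inner <- 30:(n2 - 30)
  expect_lt(mean(abs(aligned[inner, inner] - big[inner, inner])), 0.02)
})

test_that("estimate_rigid rejects unusable inputs", {
  expect_error(estimate_rigid(matrix(0.5, 64, 64), matrix(0.4, 64, 64)),
               "constant")
  expect_error(estimate_rigid(matrix(runif(64^2), 64, 64),
                              matrix(runif(32^2), 32, 32)))
})
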