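# Sparsemax, Branch localization, affine inference/constraints, grids and
# the linearized sampler.

test_that("sparsemax matches closed forms and stays on the simplex", {
  expect_equal(sparsemax(rep(1, 4)), rep(0.25, 4))
  expect_equal(sparsemax(c(0.6, 0)), c(0.8, 0.2))
  # a value exceeding all others by >= 1 wins outright
  expect_equal(sparsemax(c(2.1, 1, 0.5, 0.2, 1.1)), c(1, 0, 0, 0, 0))
  set.seed(4)
  for (i in 1:50) {
    z <- rnorm(sample(2:6, 1), sd = 2)
    p <- sparsemax(z)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
    # shift invariance and order preservation
    expect_equal(sparsemax(z + 3.7), p)
    expect_true(all(diff(p[order(z)]) >= -1e-12))
  }
  expect_error(sparsemax(numeric(0)), "empty")
})

test_that("sparsemax equals the brute-force simplex projection", {
  set.seed(5)
  for (i in 1:200) {
    z <- rnorm(sample(2:6, 1), sd = runif(1, 0.2, 3))
    expect_equal(sparsemax(z), simplex_project_bruteforce(z),
                 tolerance = 1e-10)
  }
})

test_that("infer_affine_params follows the expected-coordinate reading", {
  n <- 56
  u <- magnet:::cell_centers(n)
  # point mass: zero spread, translation at the cell center
  m <- matrix(0, n, n); m[20, 40] <- 1
  r <- infer_affine_params(m)
  expect_equal(r$s_raw, 0)
  expect_equal(r$tx_raw, u[40])
  expect_equal(r$ty_raw, u[20])
  # uniform map: centered, spread ~ 1 (independent double-loop oracle)
  m <- matrix(1 / n^2, n, n)
  r <- infer_affine_params(m)
  expect_equal(r$tx_raw, 0); expect_equal(r$ty_raw, 0)
  oracle <- 0
  for (i in 1:n) for (j in 1:n) oracle <- oracle + (abs(u[j]) + abs(u[i])) / n^2
  expect_equal(r$s_raw, oracle)
  expect_equal(oracle, 2 * mean(abs(u)))   # ~ 1.0
  # left-half mass pulls tx negative
  m <- matrix(0, n, n); m[, 1:(n / 2)] <- 1 / (n * n / 2)
  expect_lt(infer_affine_params(m)$tx_raw, 0)
  # mirror equivariance: flipping about the vertical axis negates tx,
  # preserves s
  set.seed(6)
  z <- matrix(rexp(n * n), n, n); z <- z / sum(z)
  a <- infer_affine_params(z)
  b <- infer_affine_params(z[, n:1])
  expect_equal(b$tx_raw, -a$tx_raw)
  expect_equal(b$s_raw, a$s_raw)
  expect_error(infer_affine_params(z * 2), "normalized")
})

test_that("constrain_params applies the floor / tanh bounds and Eq-4 layout", {
  p <- constrain_params(0.01, 0, 1)
  expect_equal(p$s, 0.05)
  expect_equal(p$tx, 0)
  expect_equal(p$ty, tanh(1))
  expect_equal(p$theta, matrix(c(0.05, 0, 0, 0.05, 0, tanh(1)), 2, 3))
  # monotone in each argument, outputs bounded
  set.seed(7)
  s <- sort(runif(20, -1, 3)); t <- sort(rnorm(20, sd = 3))
  ps <- sapply(s, function(v) constrain_params(v, 0, 0)$s)
  pt <- sapply(t, function(v) constrain_params(1, v, 0)$tx)
  expect_true(all(diff(ps) >= 0) && all(ps >= 0.05))
  expect_true(all(diff(pt) >= 0) && all(abs(pt) < 1))
})

test_that("make_grid maps the meshgrid through theta", {
  g <- make_grid(affine_params(1, 0, 0), 8)
  expect_equal(range(g$gx), c(-1, 1))
  expect_equal(range(g$gy), c(-1, 1))
  expect_equal(g$gx[1, ], seq(-1, 1, length.out = 8))
  g2 <- make_grid(affine_params(0.5, 0, 0), 8)
  expect_equal(range(g2$gx), c(-0.5, 0.5))
  expect_equal(range(g2$gy), c(-0.5, 0.5))
  g3 <- make_grid(affine_params(0.5, 0.5, 0), 8)
  expect_equal(range(g3$gx), c(0, 1))
  expect_equal(range(g3$gy), c(-0.5, 0.5))
})

test_that("localize yields a normalized map; slots differ; symmetry holds", {
  model <- magnet_init(desk_config(), seed = 2)
  view <- grey_filter(array(runif(56 * 56 * 3), dim = c(56, 56, 3)), tau = 0)
  m1 <- localize(view, model, "I11")
  expect_identical(dim(m1), c(56L, 56L, 3L)[1:2])
  expect_equal(sum(m1), 1)
  expect_true(all(m1 >= 0))
  # patch-specific branches: another slot gives a different map
  m2 <- localize(view, model, "I12")
  expect_gt(max(abs(m1 - m2)), 1e-8)
  # constant input: away from the zero-padded convolution borders the
  # scores are spatially constant, so the map is flat over the interior
  mc <- localize(array(0.5, dim = c(56, 56, 3)), model, "I11")
  expect_lt(diff(range(mc[9:48, 9:48])), 1e-9)
})

test_that("linearized sampling reconstructs, degrades gracefully, matches
           the bilinear oracle in the small-noise regime", {
  set.seed(8)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  # identity grid at the native resolution reproduces the image
  g <- make_grid(affine_params(1, 0, 0), 8)
  out <- linearized_sample(img, g, k_aux = 8, noise_sd = 1e-6)
  expect_lt(max(abs(out - img)), 1e-3)
  # constant image: exactly constant output for any in-bounds grid
  cimg <- array(0.42, dim = c(8, 8, 3))
  g2 <- make_grid(affine_params(0.4, 0.1, -0.2), 8)
  expect_equal(linearized_sample(cimg, g2, 8, 0.01),
               array(0.42, dim = c(8, 8, 3)))
  # random in-bounds grid vs dense bilinear oracle
  gx <- runif(64, -0.7, 0.7); gy <- runif(64, -0.7, 0.7)
  out2 <- magnet:::cpp_linsample_fwd(img, gx, gy, 8L, 1e-4, 99)
  expect_lt(max(abs(out2 - bilinear_oracle(img, gx, gy))), 1e-2)
  # zero noise is exactly plain bilinear (degenerate-fit fallback)
  out3 <- magnet:::cpp_linsample_fwd(img, gx, gy, 8L, 0, 99)
  expect_equal(as.numeric(out3), as.numeric(bilinear_oracle(img, gx, gy)),
               tolerance = 1e-12)
})

test_that("linearized gradients survive heavy minification; bilinear's collapse", {
  # Gradient of the mean sampled intensity w.r.t. the scale s by central
  # finite differences through each sampler. A 16-point grid over a 96-px
  # image samples at ~8x minification when s = 1 (each output point skips
  # ~6 source pixels) and at ~native resolution when s = 1/8.
  set.seed(9)
  coarse <- array(runif(6 * 6 * 3), dim = c(6, 6, 3))
  img <- magnet:::cpp_resize_bilinear(coarse, 96, 96)
  grad_wrt_s <- function(s, sampler) {
    f <- function(sv) {
      g <- make_grid(affine_params(sv, 0.05, -0.03), 16)
      mean(sampler(img, g))
    }
    (f(s + 1e-4) - f(s - 1e-4)) / 2e-4
  }
  lin <- function(im, g) {
    set.seed(10)
    linearized_sample(im, g, k_aux = 8, noise_sd = 1 / 16)
  }
  bil <- function(im, g) bilinear_sample(im, g)
  lin_ratio <- abs(grad_wrt_s(1, lin)) / abs(grad_wrt_s(0.125, lin))
  bil_ratio <- abs(grad_wrt_s(1, bil)) / abs(grad_wrt_s(0.125, bil))
  expect_gt(lin_ratio, 0.1)       # within a factor of 10 of the 1x case
  expect_lt(bil_ratio, lin_ratio) # bilinear degrades by more under scaling
})
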