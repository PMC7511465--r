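# The convolution engine and distance transform are the numeric foundation
# of the package; they are checked here against naive reference
# implementations and finite differences.

test_that("conv2d forward matches a naive direct convolution", {
  set.seed(21)
  x <- array(rnorm(5 * 6 * 2 * 3), c(5, 6, 2, 3))
  w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  b <- rnorm(4)
  expect_equal(mvseg:::cpp_conv2d_fwd(x, w, b), bf_conv2d(x, w, b),
               tolerance = 1e-12)
  w1 <- array(rnorm(1 * 1 * 2 * 3), c(1, 1, 2, 3))
  expect_equal(mvseg:::cpp_conv2d_fwd(x, w1, numeric(3)),
               bf_conv2d(x, w1, numeric(3)), tolerance = 1e-12)
})

test_that("max pooling records argmax positions consistently", {
  set.seed(22)
  x <- array(rnorm(6 * 4 * 2 * 2), c(6, 4, 2, 2))
  p <- mvseg:::cpp_maxpool2_fwd(x)
  expect_identical(dim(p$y), c(3L, 2L, 2L, 2L))
  expect_equal(as.vector(p$y), x[p$idx])
  # backward routes gradient only to the argmax voxels
  dy <- array(rnorm(length(p$y)), dim(p$y))
  dx <- mvseg:::cpp_maxpool2_bwd(p$idx, dy, dim(x))
  expect_equal(sum(dx), sum(dy))
  expect_equal(dx[p$idx], as.vector(dy))
})

test_that("upsampling and its adjoint are consistent", {
  set.seed(23)
  x <- array(rnorm(3 * 2 * 2 * 1), c(3, 2, 2, 1))
  y <- mvseg:::cpp_upsample2_fwd(x)
  expect_identical(dim(y), c(6L, 4L, 2L, 1L))
  expect_equal(y[1:2, 1:2, 1, 1], matrix(x[1, 1, 1, 1], 2, 2))
  # <dy, U x> == <U^T dy, x> (adjoint identity)
  dy <- array(rnorm(length(y)), dim(y))
  expect_equal(sum(dy * y), sum(mvseg:::cpp_upsample2_bwd(dy) * x),
               tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(24)
  cfg <- list(depth = 2L, base_filters = 3L, seed = 99L)
  w <- mvseg:::unet_init(cfg)
  # perturb biases away from zero so no ReLU pre-activation sits exactly at
  # its kink (where the subgradient and the central difference may differ)
  for (nm in grep("_b$", names(w), value = TRUE))
    w[[nm]] <- w[[nm]] + rnorm(length(w[[nm]]), sd = 0.05)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  f <- mvseg:::unet_forward(w, x, cfg$depth, training = TRUE)
  bl <- mvseg:::bce_with_logits(f$logits, y)
  g <- mvseg:::unet_backward(w, f$cache, bl$dlogits, cfg$depth)
  loss_at <- function(w) {
    f <- mvseg:::unet_forward(w, x, cfg$depth)
    mvseg:::bce_with_logits(f$logits, y, with_grad = FALSE)$loss
  }
  eps <- 1e-6
  for (nm in names(w)) {
    idx <- sample(length(w[[nm]]), min(3, length(w[[nm]])))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("the exact distance transform matches brute force, anisotropic", {
  for (s in 1:12) {
    set.seed(s)
    dims <- sample(3:8, 3, replace = TRUE)
    sp <- runif(3, 0.4, 2)
    m <- array(rbinom(prod(dims), 1, 0.15), dims)
    if (sum(m) == 0) m[1, 1, 1] <- 1
    got <- mvseg:::cpp_edt_sq(m * 1, sp)
    expect_equal(got, bf_edt_sq(m, sp), tolerance = 1e-9)
  }
})
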