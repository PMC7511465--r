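test_that("Hounsfield windowing maps the 200/800 window linearly with clamping", {
  hu <- volume(array(c(-1000, -200, 0, 200, 400, 600, 1200, 50), c(2, 2, 2)))
  w <- apply_window(hu, level = 200, width = 800)
  expect_equal(w$data[1, 1, 1], 0)           # air clamps below
  expect_equal(w$data[2, 1, 1], 0)           # lower window bound
  expect_equal(w$data[2, 2, 1], 127.5)       # window midpoint
  expect_equal(w$data[2, 1, 2], 255)         # upper window bound
  expect_equal(w$data[1, 2, 2], 255)         # clamps above
  expect_equal(w$data[1, 2, 1], (0 + 200) / 800 * 255)
  expect_error(apply_window(hu, width = 0), "width")
  expect_error(apply_window(binarize_volume(prob_vol(array(0.5, c(2, 2, 2))), 0.4)),
               "intensity")
})

test_that("windowing is monotone non-decreasing in input HU", {
  set.seed(5)
  x <- sort(runif(64, -1500, 2000))
  w <- apply_window(volume(array(x, c(4, 4, 4))))
  expect_true(all(diff(as.vector(w$data)) >= 0))
})

test_that("resampling preserves physical extent and slice-count arithmetic", {
  set.seed(7)
  v <- volume(array(rnorm(10 * 6 * 6), c(10, 6, 6)), spacing = c(1.24, 0.73, 0.73))
  r <- resample_volume(v, c(0.62, 0.73, 0.73))
  expect_identical(dim(r), c(20L, 6L, 6L))   # 10 * 1.24 / 0.62
  expect_equal(r$spacing, c(0.62, 0.73, 0.73))
  # extent per axis preserved to within one output voxel
  expect_lt(abs(20 * 0.62 - 10 * 1.24), 0.62 + 1e-12)
  expect_error(resample_volume(v, c(0, 1, 1)), "positive")
})

test_that("resampling at the native spacing is the identity", {
  v <- volume(array(rnorm(60), c(5, 4, 3)), spacing = c(1, 2, 3))
  expect_identical(resample_volume(v, c(1, 2, 3))$data, v$data)
})

test_that("label volumes stay binary under resampling", {
  m <- random_mask_vol(c(9, 7, 5), 0.4, seed = 2)
  m$spacing <- c(1.3, 0.9, 1.1)
  r <- resample_volume(m, c(0.7, 0.7, 0.7))
  expect_true(all(r$data %in% c(0, 1)))
  expect_identical(r$role, "label")
})

test_that("round-trip resampling approximately recovers a smooth volume", {
  z <- array(0, c(12, 12, 12))
  for (k in 1:12) z[k, , ] <- outer(sin((1:12) / 3), cos((1:12) / 4)) + k / 6
  v <- volume(z, spacing = c(1, 1, 1))
  back <- resample_volume(resample_volume(v, c(0.7, 0.8, 0.9)), c(1, 1, 1))
  expect_identical(dim(back), dim(v))
  expect_lt(mean(abs(back$data - v$data)), 0.05 * diff(range(z)))
})

test_that("in-plane down-sampling block-averages and rescales spacing", {
  checker <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  arr <- aperm(array(rep(checker, 3), c(8, 8, 3)), c(3, 1, 2))  # (z, y, x)
  v <- volume(arr, spacing = c(2, 1, 1))
  d2 <- downsample_inplane(v, 2)
  expect_identical(dim(d2), c(3L, 4L, 4L))
  expect_true(all(abs(d2$data - 0.5) < 1e-12))   # checkerboard block mean
  expect_equal(d2$spacing, c(2, 2, 2))
  expect_identical(downsample_inplane(v, 1)$data, v$data)
  expect_error(downsample_inplane(v, 0), "factor")
})

test_that("a 512x512 in-plane grid down-samples to 128x128 at factor 4", {
  v <- volume(array(0, c(2, 512, 512)), spacing = c(1, 0.73, 0.73))
  d <- downsample_inplane(v, 4)
  expect_identical(dim(d), c(2L, 128L, 128L))
  expect_equal(d$spacing[2:3], c(0.73, 0.73) * 4)
  lab <- random_mask_vol(c(2, 512, 512), 0.2, seed = 3)
  expect_true(all(downsample_inplane(lab, 4)$data %in% c(0, 1)))
})

test_that("degenerate augmentation intervals give the identity transform", {
  set.seed(9)
  img <- matrix(rnorm(20 * 24), 20, 24)
  msk <- matrix(rbinom(20 * 24, 1, 0.3), 20, 24)
  ap <- augment_params(rotation_deg = c(0, 0), shift_x_px = c(0, 0),
                       shift_y_px = c(0, 0), zoom = c(1, 1), seed = 4)
  out <- augment_pair(img, msk, ap)
  expect_equal(out$image, img)
  expect_identical(out$mask, msk * 1)
})

test_that("augmentation is deterministic given the seed and keeps masks binary", {
  set.seed(10)
  img <- matrix(rnorm(32 * 32), 32, 32)
  msk <- matrix(rbinom(32 * 32, 1, 0.2), 32, 32)
  ap <- augment_params(seed = 77)
  a <- augment_pair(img, msk, ap)
  b <- augment_pair(img, msk, ap)
  expect_identical(a, b)
  for (s in 1:10) {
    ap$seed <- s
    out <- augment_pair(img, msk, ap)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_identical(dim(out$image), dim(img))
  }
})

test_that("a degenerate 90-degree rotation interval rotates exactly", {
  img <- matrix(as.numeric(1:25), 5, 5)
  ap <- augment_params(rotation_deg = c(90, 90), shift_x_px = c(0, 0),
                       shift_y_px = c(0, 0), zoom = c(1, 1), seed = 1)
  out <- augment_pair(img, (img > 12) * 1, ap)
  # inverse-mapped rotation by +90 deg about the centre of a 5x5 grid
  expected <- matrix(0, 5, 5)
  for (r in 1:5) for (cc in 1:5) {
    sr <- (cc - 3) + 3; sc <- -(r - 3) + 3
    expected[r, cc] <- img[sr, sc]
  }
  expect_equal(out$image, expected)
})

test_that("augmentation rejects mismatched shapes and bad intervals", {
  expect_error(augment_pair(matrix(0, 3, 3), matrix(0, 3, 4), augment_params()),
               "identical shape")
  expect_error(augment_params(rotation_deg = c(10, -10)), "interval")
  expect_error(augment_params(zoom = c(-0.5, 1)), "positive")
})
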