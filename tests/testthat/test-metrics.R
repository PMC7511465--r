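test_that("dice and jaccard follow their set formulas on crafted masks", {
  a <- array(0, c(3, 3, 3)); b <- array(0, c(3, 3, 3))
  a[1, 1:2, 1:2] <- 1                      # |GT| = 4
  b[1, 1:2, 1] <- 1; b[2, 1:2, 1] <- 1     # |P| = 4, overlap 2
  expect_equal(dice(label_vol(a), label_vol(b)), 0.5)
  expect_equal(jaccard(label_vol(a), label_vol(b)), 2 / 6)
  expect_equal(dice(label_vol(a), label_vol(a)), 1)
  expect_equal(jaccard(label_vol(a), label_vol(a)), 1)
  disj <- array(0, c(3, 3, 3)); disj[3, 3, 3] <- 1
  expect_equal(dice(label_vol(a), label_vol(disj)), 0)
  z <- label_vol(array(0, c(3, 3, 3)))
  expect_equal(dice(z, z), 1)              # both-empty convention
  expect_equal(jaccard(z, z), 1)
  expect_equal(dice(z, label_vol(disj)), 0)
  expect_error(dice(label_vol(a), label_vol(array(0, c(2, 3, 3)))), "shape")
  expect_error(dice(label_vol(a), prob_vol(array(0.5, c(3, 3, 3)))), "binary")
})

test_that("overlap metrics match the set-count oracle on random masks", {
  for (s in 1:200) {
    set.seed(s)
    p <- runif(2, 0.05, 0.6)
    a <- array(rbinom(16^3, 1, p[1]), c(16, 16, 16))
    b <- array(rbinom(16^3, 1, p[2]), c(16, 16, 16))
    expect_identical(dice(label_vol(a), label_vol(b)), bf_dice(a, b))
    expect_identical(jaccard(label_vol(a), label_vol(b)), bf_jaccard(a, b))
  }
})

test_that("dice and jaccard are symmetric and algebraically linked", {
  for (s in 1:25) {
    a <- random_mask_vol(c(10, 10, 10), 0.3, seed = s)
    b <- random_mask_vol(c(10, 10, 10), 0.4, seed = s + 100)
    expect_identical(dice(a, b), dice(b, a))
    expect_identical(jaccard(a, b), jaccard(b, a))
    j <- jaccard(a, b)
    expect_equal(dice(a, b), 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("growing pred by one ground-truth voxel never decreases dice", {
  set.seed(42)
  for (rep in 1:20) {
    gt <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
    pred <- gt * rbinom(8^3, 1, 0.5)            # subset of gt
    missing <- which(gt == 1 & pred == 0)
    if (length(missing) == 0) next
    d0 <- dice(label_vol(gt), label_vol(pred))
    pred[sample(missing, 1)] <- 1
    expect_gte(dice(label_vol(gt), label_vol(pred)), d0)
  }
})

test_that("surface distances reproduce hand-computable geometries", {
  a <- array(0, c(9, 5, 5)); a[3, 3, 3] <- 1
  b <- array(0, c(9, 5, 5)); b[6, 3, 3] <- 1
  d <- surface_distances(label_vol(a), label_vol(b))
  expect_equal(d$mean, 3); expect_equal(d$sd, 0); expect_equal(d$max, 3)
  # anisotropic spacing: a 3-voxel z shift at 0.62 mm slices is 1.86 mm
  d2 <- surface_distances(label_vol(a, spacing = c(0.62, 0.73, 0.73)),
                          label_vol(b, spacing = c(0.62, 0.73, 0.73)))
  expect_equal(d2$mean, 1.86, tolerance = 1e-12)
  same <- surface_distances(label_vol(a), label_vol(a))
  expect_equal(unlist(same), c(mean = 0, sd = 0, max = 0))
  expect_error(surface_distances(label_vol(a), label_vol(array(0, c(9, 5, 5)))),
               "empty")
})

test_that("surface distances match the all-pairs brute force on random masks", {
  for (s in 1:20) {
    set.seed(s)
    dims <- sample(4:10, 3, replace = TRUE)
    sp <- runif(3, 0.5, 1.5)
    a <- array(rbinom(prod(dims), 1, 0.3), dims)
    b <- array(rbinom(prod(dims), 1, 0.3), dims)
    if (sum(a) == 0 || sum(b) == 0) next
    got <- surface_distances(label_vol(a, spacing = sp), label_vol(b, spacing = sp))
    want <- bf_surface_distances(a, b, sp)
    expect_equal(got$mean, want$mean, tolerance = 1e-9)
    expect_equal(got$sd, want$sd, tolerance = 1e-9)
    expect_equal(got$max, want$max, tolerance = 1e-9)
    # symmetric in its arguments
    swapped <- surface_distances(label_vol(b, spacing = sp), label_vol(a, spacing = sp))
    expect_equal(got$mean, swapped$mean, tolerance = 1e-12)
    expect_equal(got$max, swapped$max, tolerance = 1e-12)
  }
})

test_that("evaluate_case bundles the metrics into a consistent report row", {
  a <- random_mask_vol(c(8, 8, 8), 0.3, seed = 1)
  r <- evaluate_case(a, a, "self")
  expect_identical(r$case_id, "self")
  expect_equal(r$dsc, 1); expect_equal(r$jac, 1)
  expect_equal(r$mean_sd_mm, 0); expect_equal(r$max_sd_mm, 0)
  b <- random_mask_vol(c(8, 8, 8), 0.3, seed = 2)
  r2 <- evaluate_case(a, b, "x")
  expect_equal(r2$dsc, 2 * r2$jac / (1 + r2$jac), tolerance = 1e-12)
  expect_lte(r2$mean_sd_mm, r2$max_sd_mm)
})
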