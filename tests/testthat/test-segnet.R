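test_that("model configs enforce divisibility and positivity", {
  expect_error(seg_model_config(depth = 2, input_shape = c(63, 64)),
               "divisible")
  expect_error(seg_model_config(depth = 0, input_shape = c(16, 16)), ">= 1")
  cfg <- seg_model_config(depth = 2, base_filters = 4, input_shape = c(16, 16))
  expect_s3_class(cfg, "mvseg_model_config")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(patience = -1), "patience")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("an untrained model outputs per-pixel probabilities of input shape", {
  cfg <- seg_model_config(depth = 2, base_filters = 8, input_shape = c(16, 24),
                          seed = 5)
  m <- build_model(cfg)
  set.seed(1)
  imgs <- array(rnorm(16 * 24 * 3), c(16, 24, 3))
  p <- mvseg:::predict_slices(m, imgs)
  expect_identical(dim(p), c(16L, 24L, 3L))
  expect_true(all(p >= 0 & p <= 1))
  # all-zero input still yields finite probabilities
  p0 <- mvseg:::predict_slices(m, array(0, c(16, 24, 2)))
  expect_true(all(is.finite(p0)))
  # identical seeds give identical initial predictions
  m2 <- build_model(cfg)
  expect_identical(mvseg:::predict_slices(m2, imgs), p)
  # a different seed gives different weights
  m3 <- build_model(seg_model_config(depth = 2, base_filters = 8,
                                     input_shape = c(16, 24), seed = 6))
  expect_false(identical(m3$weights, m$weights))
  expect_error(mvseg:::predict_slices(m, array(0, c(8, 24, 2))), "match")
})

# A small separable task: bright disc on dark background, label = disc.
disc_slice_set <- function(n, hw = 16L, seed = 1) {
  set.seed(seed)
  imgs <- array(0, c(hw, hw, n)); msks <- array(0, c(hw, hw, n))
  for (i in seq_len(n)) {
    ctr <- runif(2, 6, hw - 5)
    r <- runif(1, 2.5, 4)
    dist2 <- outer((seq_len(hw) - ctr[1])^2, (seq_len(hw) - ctr[2])^2, `+`)
    msks[, , i] <- (dist2 <= r^2) * 1
    imgs[, , i] <- msks[, , i] * 0.8 + rnorm(hw * hw, 0, 0.08)
  }
  list(images = imgs, masks = msks)
}

test_that("training reduces the loss and restores the best-validation epoch", {
  tr <- disc_slice_set(20, seed = 2)
  va <- disc_slice_set(6, seed = 3)
  m <- build_model(seg_model_config(depth = 2, base_filters = 8,
                                    input_shape = c(16, 16), seed = 1))
  tc <- train_config(learning_rate = 1e-3, batch_size = 10, patience = 15,
                     max_epochs = 10, augment = NULL, seed = 7)
  fit <- train(m, tr, va, tc)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(fit$trained)
  # returned weights are the best-validation-epoch weights
  relisted <- fit
  val_now <- local({
    x <- array(va$images, c(16, 16, 1, dim(va$images)[3]))
    y <- array(va$masks, c(16, 16, 1, dim(va$masks)[3]))
    f <- mvseg:::unet_forward(relisted$weights, x, 2L)
    mvseg:::bce_with_logits(f$logits, y, with_grad = FALSE)$loss
  })
  expect_equal(val_now, min(h$val_loss), tolerance = 1e-10)
  expect_true(all(min(h$val_loss) <= h$val_loss))
})

test_that("training is deterministic under fixed seeds", {
  tr <- disc_slice_set(12, seed = 4)
  va <- disc_slice_set(4, seed = 5)
  mk <- function() {
    m <- build_model(seg_model_config(depth = 2, base_filters = 4,
                                      input_shape = c(16, 16), seed = 3))
    tc <- train_config(learning_rate = 1e-3, batch_size = 6, max_epochs = 3,
                       steps_per_epoch = 4,
                       augment = augment_params(rotation_deg = c(-7, 7),
                                                shift_x_px = c(-2, 2),
                                                shift_y_px = c(-2, 2)),
                       seed = 11)
    train(m, tr, va, tc)
  }
  a <- mk(); b <- mk()
  expect_identical(a$history, b$history)
  expect_identical(a$weights, b$weights)
})

test_that("early stopping with patience 0 stops at the first non-improvement", {
  tr <- disc_slice_set(12, seed = 6)
  va <- disc_slice_set(4, seed = 7)
  m <- build_model(seg_model_config(depth = 2, base_filters = 4,
                                    input_shape = c(16, 16), seed = 2))
  tc <- train_config(learning_rate = 5e-2, batch_size = 6, patience = 0,
                     max_epochs = 12, steps_per_epoch = 4, augment = NULL,
                     seed = 9)
  fit <- train(m, tr, va, tc)
  h <- fit$history
  if (nrow(h) < 12) {
    # every epoch but the last improved on the running best
    running <- cummin(h$val_loss)
    expect_true(all(h$val_loss[-nrow(h)] == running[-nrow(h)]))
    expect_gte(h$val_loss[nrow(h)], min(h$val_loss[-nrow(h)]))
  }
  expect_error(train(m, list(images = array(0, c(16, 16, 0)),
                             masks = array(0, c(16, 16, 0))), va, tc),
               "n >= 1")
})

test_that("predict_stack is per-slice independent and order-preserving", {
  v <- volume(array(rnorm(8 * 16 * 16), c(8, 16, 16)))
  m <- build_model(seg_model_config(depth = 2, base_filters = 4,
                                    input_shape = c(16, 16), seed = 4))
  stacks <- slice_views(v)
  p <- predict_stack(m, stacks$axial)
  expect_s3_class(p, "mvseg_volume")
  expect_identical(p$role, "probability")
  expect_identical(dim(p), dim(v))
  # permuting slice order permutes the output identically
  perm <- sample(8)
  st2 <- stacks$axial
  st2$slices <- st2$slices[, , perm]
  p2 <- predict_stack(m, st2)
  expect_equal(p2$data, p$data[perm, , ], tolerance = 1e-12)
})

test_that("select_threshold equals exhaustive evaluation and breaks ties low", {
  # binary probability maps: every threshold gives Dice 1 -> smallest wins
  gt <- random_mask_vol(c(6, 6, 6), 0.3, seed = 1)
  pv <- prob_vol(gt$data)
  expect_identical(select_threshold(list(pv), list(gt), c(0.75, 0.25, 0.5)),
                   0.25)
  # crafted two-case fixture with a known optimum
  gt1 <- label_vol(array(c(rep(1, 40), rep(0, 176)), c(6, 6, 6)))
  p1 <- array(0.05, c(6, 6, 6)); p1[1:40] <- 0.45; p1[41:80] <- 0.35
  gt2 <- label_vol(array(c(rep(1, 60), rep(0, 156)), c(6, 6, 6)))
  p2 <- array(0.02, c(6, 6, 6)); p2[1:60] <- 0.55; p2[61:70] <- 0.42
  probs <- list(prob_vol(p1), prob_vol(p2)); gts <- list(gt1, gt2)
  grid <- seq(0.05, 0.95, by = 0.05)
  exhaustive <- vapply(grid, function(t) {
    mean(c(bf_dice(gt1$data, (p1 >= t) * 1), bf_dice(gt2$data, (p2 >= t) * 1)))
  }, numeric(1))
  expect_identical(select_threshold(probs, gts, grid),
                   grid[which.max(exhaustive)])
  expect_identical(select_threshold(probs, gts, grid), 0.45)
  expect_error(select_threshold(probs, gts, numeric(0)), "nonempty")
  expect_error(select_threshold(probs, gts, c(0, 0.5)), "\\(0, 1\\)")
  # the default grid has 0.05 granularity and contains 0.4 and 0.45
  expect_true(all(c(0.4, 0.45) %in% seq(0.05, 0.95, by = 0.05)))
})
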