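#' Segmentation model configuration
#'
#' Architecture hyperparameters of the 2D encoder-decoder segmenter: a
#' classic U-Net topology with two 3x3 convolution + ReLU layers per level,
#' 2x2 max pooling, a mirrored decoder with nearest-neighbour upsampling,
#' skip connections, and a 1x1 sigmoid head.
#'
#' @param depth number of encoder levels (>= 1); feature-map width doubles
#'   per level.
#' @param base_filters channels at the first level (>= 1).
#' @param input_shape `(h, w)` of the input slices; both must be divisible
#'   by `2^depth`.
#' @param seed integer seed for deterministic weight initialization.
#' @return An object of class `mvseg_model_config`.
#' @export
seg_model_config <- function(depth = 2L, base_filters = 8L, input_shape,
                             seed = 1L) {
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  input_shape <- as.integer(input_shape)
  if (depth < 1L || base_filters < 1L)
    stop("`depth` and `base_filters` must be >= 1", call. = FALSE)
  if (length(input_shape) != 2L || any(input_shape < 2^depth))
    stop("`input_shape` must be (h, w)", call. = FALSE)
  if (any(input_shape %% 2L^depth != 0L))
    stop(sprintf("input shape (%d, %d) must be divisible by 2^depth = %d",
                 input_shape[1], input_shape[2], 2L^depth), call. = FALSE)
  structure(list(depth = depth, base_filters = base_filters,
                 input_shape = input_shape, seed = as.integer(seed)),
            class = "mvseg_model_config")
}

#' Training configuration
#'
#' Optimization hyperparameters: binary cross-entropy loss, Adam with
#' learning rate 1e-4 by default, mini-batches sampled randomly from all
#' training slices (empty-mask slices included), on-the-fly augmentation,
#' and early stopping on validation loss with best-epoch weight restore.
#'
#' @param learning_rate Adam step size, > 0.
#' @param batch_size slices per mini-batch (>= 1); 20 was used for the
#'   coarse stage and 10 for the single-view stages.
#' @param patience epochs of non-improving validation loss tolerated before
#'   stopping (>= 0).
#' @param max_epochs hard epoch cap.
#' @param steps_per_epoch optional cap on mini-batches per epoch; `NULL`
#'   means one pass worth (`ceiling(n_slices / batch_size)`).
#' @param augment an [augment_params()] object, or `NULL` to disable.
#' @param loss,optimizer currently `"binary_cross_entropy"` and `"adam"`.
#' @param seed integer seed; a fixed seed makes the whole run reproducible.
#' @return An object of class `mvseg_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 10L,
                         patience = 15L, max_epochs = 50L,
                         steps_per_epoch = NULL, augment = augment_params(),
                         loss = "binary_cross_entropy", optimizer = "adam",
                         seed = 1L) {
  loss <- match.arg(loss); optimizer <- match.arg(optimizer)
  if (!is.finite(learning_rate) || learning_rate <= 0)
    stop("`learning_rate` must be > 0", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (patience < 0L) stop("`patience` must be >= 0", call. = FALSE)
  if (max_epochs < 1L) stop("`max_epochs` must be >= 1", call. = FALSE)
  structure(list(loss = loss, optimizer = optimizer,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 steps_per_epoch = if (is.null(steps_per_epoch)) NULL else
                   as.integer(steps_per_epoch),
                 augment = augment, seed = as.integer(seed)),
            class = "mvseg_train_config")
}

#' Build an (untrained) segmentation model
#'
#' Instantiates the U-Net weights for a [seg_model_config()]. The model maps
#' an `(h, w)` single-channel slice to an `(h, w)` per-pixel probability
#' map; initialization is He-normal and deterministic given `cfg$seed`.
#'
#' @param cfg a [seg_model_config()].
#' @return An object of class `mvseg_model`.
#' @export
build_model <- function(cfg) {
  if (!inherits(cfg, "mvseg_model_config"))
    stop("`cfg` must come from seg_model_config()", call. = FALSE)
  structure(list(config = cfg, weights = unet_init(cfg),
                 history = NULL, trained = FALSE),
            class = "mvseg_model")
}

#' @export
print.mvseg_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf("<mvseg_model> U-Net depth %d, %d base filters, input %dx%d (%s)\n",
              cfg$depth, cfg$base_filters, cfg$input_shape[1],
              cfg$input_shape[2],
              if (x$trained) sprintf("trained, %d epochs", nrow(x$history))
              else "untrained"))
  cat(sprintf("  %d parameters\n", np))
  invisible(x)
}

# Batched sigmoid-probability inference on an (H, W, N) slice array.
predict_slices <- function(model, images, chunk = 16L) {
  cfg <- model$config
  d <- dim(images)
  if (length(d) == 2L) { images <- array(images, c(d, 1L)); d <- dim(images) }
  if (d[1] != cfg$input_shape[1] || d[2] != cfg$input_shape[2])
    stop(sprintf("slice shape (%d, %d) does not match model input (%d, %d)",
                 d[1], d[2], cfg$input_shape[1], cfg$input_shape[2]),
         call. = FALSE)
  out <- array(0, d)
  for (start in seq(1L, d[3], by = chunk)) {
    idx <- start:min(start + chunk - 1L, d[3])
    x <- array(images[, , idx], c(d[1], d[2], 1L, length(idx)))
    f <- unet_forward(model$weights, x, cfg$depth)
    out[, , idx] <- sigmoid(f$logits)
  }
  out
}

#' Train a segmentation model
#'
#' Mini-batch gradient training: each step samples `batch_size` slices
#' uniformly (with replacement when the set is smaller than a batch) from
#' all training slices, augments each image/mask pair on the fly, and takes
#' one Adam step on the binary cross-entropy. After each epoch the
#' validation loss is computed; training stops when it has not improved for
#' `patience` consecutive epochs or at `max_epochs`, and the weights of the
#' best-validation epoch are restored. Deterministic given `tc$seed`.
#'
#' @param model an untrained or previously trained [build_model()] object.
#' @param train_slices,val_slices slice sets: `list(images =, masks =)`
#'   with `(h, w, n)` arrays, images on a roughly unit scale, masks binary.
#' @param tc a [train_config()].
#' @return The trained `mvseg_model`, with `history` holding per-epoch
#'   train/validation loss.
#' @export
train <- function(model, train_slices, val_slices, tc) {
  if (!inherits(model, "mvseg_model")) stop("`model` must be a mvseg_model", call. = FALSE)
  if (!inherits(tc, "mvseg_train_config")) stop("`tc` must come from train_config()", call. = FALSE)
  check_slice_set <- function(s, nm) {
    if (!is.list(s) || is.null(s$images) || is.null(s$masks) ||
        length(dim(s$images)) != 3L || dim(s$images)[3] < 1L)
      stop("`", nm, "` must be list(images, masks) with (h, w, n) arrays and n >= 1",
           call. = FALSE)
    if (!identical(dim(s$images), dim(s$masks)))
      stop("`", nm, "`: images and masks differ in shape", call. = FALSE)
    hw <- dim(s$images)[1:2]
    if (!identical(as.integer(hw), model$config$input_shape))
      stop("`", nm, "` slice shape does not match model input shape", call. = FALSE)
  }
  check_slice_set(train_slices, "train_slices")
  check_slice_set(val_slices, "val_slices")

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(tc$seed)

  h <- model$config$input_shape[1]; w <- model$config$input_shape[2]
  n <- dim(train_slices$images)[3]
  depth <- model$config$depth
  bs <- tc$batch_size
  steps <- tc$steps_per_epoch %||% as.integer(ceiling(n / bs))
  weights <- model$weights
  state <- adam_init(weights)

  val_loss_of <- function(wts) {
    d <- dim(val_slices$images)
    tot <- 0
    for (start in seq(1L, d[3], by = 16L)) {
      idx <- start:min(start + 15L, d[3])
      x <- array(val_slices$images[, , idx], c(h, w, 1L, length(idx)))
      y <- array(val_slices$masks[, , idx], c(h, w, 1L, length(idx)))
      f <- unet_forward(wts, x, depth)
      tot <- tot + bce_with_logits(f$logits, y, with_grad = FALSE)$loss * length(idx)
    }
    tot / d[3]
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_loss <- Inf
  best_weights <- weights
  wait <- 0L
  for (epoch in seq_len(tc$max_epochs)) {
    ep_loss <- 0
    for (step in seq_len(steps)) {
      idx <- sample.int(n, bs, replace = n < bs)
      xb <- array(0, c(h, w, 1L, bs)); yb <- array(0, c(h, w, 1L, bs))
      aug_seeds <- if (is.null(tc$augment)) NULL else
        sample.int(2147483647L, bs)
      for (j in seq_len(bs)) {
        im <- train_slices$images[, , idx[j]]
        mk <- train_slices$masks[, , idx[j]]
        if (!is.null(tc$augment)) {
          ap <- tc$augment; ap$seed <- aug_seeds[j]
          pr <- augment_pair(im, mk, ap)
          im <- pr$image; mk <- pr$mask
        }
        xb[, , 1L, j] <- im; yb[, , 1L, j] <- mk
      }
      f <- unet_forward(weights, xb, depth, training = TRUE)
      bl <- bce_with_logits(f$logits, yb)
      grads <- unet_backward(weights, f$cache, bl$dlogits, depth)
      upd <- adam_step(weights, grads, state, tc$learning_rate)
      weights <- upd$w; state <- upd$state
      ep_loss <- ep_loss + bl$loss
    }
    vl <- val_loss_of(weights)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / steps,
                                         val_loss = vl))
    if (vl < best_loss - 1e-12) {
      best_loss <- vl
      best_weights <- weights
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > tc$patience) break
    }
  }
  model$weights <- best_weights
  model$history <- history
  model$trained <- TRUE
  model
}

#' Predict a probability volume from a view stack
#'
#' Runs per-slice inference over an ordered stack of 2D slices and
#' reassembles the per-slice probability maps into a probability
#' [volume()] on the stack's source grid. Slices are processed
#' independently, so permuting the stack order permutes the output
#' identically.
#'
#' @param model a trained [build_model()] object.
#' @param stack a view stack from [slice_views()].
#' @return A probability [volume()].
#' @export
predict_stack <- function(model, stack) {
  if (!inherits(stack, "mvseg_view_stack"))
    stop("`stack` must come from slice_views()", call. = FALSE)
  probs <- predict_slices(model, stack$slices)
  out <- stack
  out$slices <- probs
  reassemble_views(out, role = "probability")
}

#' Select the binarization threshold maximizing mean Dice
#'
#' Exhaustively evaluates every candidate threshold: each probability volume
#' is binarized at the candidate (`p >= t`), the per-case 3D Dice against
#' ground truth is computed, and the grid value maximizing the mean Dice is
#' returned. Ties are broken in favour of the smallest threshold.
#'
#' @param prob_volumes list of probability [volume()]s.
#' @param gt_masks list of label [volume()]s, shape-matched pairwise.
#' @param grid candidate thresholds in `(0, 1)`; the default is the 0.05-step
#'   grid `0.05, 0.10, ..., 0.95`.
#' @return The selected threshold (a single number from `grid`).
#' @export
select_threshold <- function(prob_volumes, gt_masks,
                             grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(grid) < 1L) stop("`grid` must be nonempty", call. = FALSE)
  if (any(grid <= 0 | grid >= 1)) stop("grid values must be in (0, 1)", call. = FALSE)
  if (length(prob_volumes) < 1L || length(prob_volumes) != length(gt_masks))
    stop("`prob_volumes` and `gt_masks` must be nonempty lists of equal length",
         call. = FALSE)
  for (i in seq_along(prob_volumes)) check_same_shape(prob_volumes[[i]], gt_masks[[i]])
  grid <- sort(grid)
  mean_dsc <- vapply(grid, function(t) {
    mean(vapply(seq_along(prob_volumes), function(i) {
      dice(gt_masks[[i]], binarize_volume(prob_volumes[[i]], t))
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(mean_dsc)]   # which.max returns the first (smallest) maximizer
}

#' Binarize a probability volume at a threshold
#'
#' @param p a probability [volume()].
#' @param t threshold; voxels with `p >= t` become foreground.
#' @return A label [volume()].
#' @export
binarize_volume <- function(p, t) {
  stop_if_not_volume(p)
  vol_like(p, (p$data >= t) * 1, role = "label")
}
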