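# End-to-end experiment orchestration: train the coarse + three single-view
# models from a phantom dataset manifest, select every binarization
# threshold on the validation split, and evaluate on the test split.

# Concatenate (h, w, n) slice arrays along the third axis.
cat3 <- function(arrs) {
  arrs <- Filter(Negate(is.null), arrs)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[3], integer(1)))
  array(unlist(arrs, use.names = FALSE), c(d[1], d[2], n))
}

# Crop a volume with an existing ROI record (zero-padded like extract_roi).
roi_crop <- function(v, roi) {
  crop <- array(0, roi$size)
  d <- dim(v$data)
  src_lo <- pmax(roi$start, 1L); src_hi <- pmin(roi$start + roi$size - 1L, d)
  dst_lo <- src_lo - roi$start + 1L; dst_hi <- src_hi - roi$start + 1L
  crop[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    v$data[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  volume(crop, spacing = v$spacing,
         origin = v$origin + (roi$start - 1L) * v$spacing, role = v$role)
}

load_case <- function(cs, cfg) {
  img <- read_volume(cs$image)
  msk <- read_volume(cs$mask, role = "label")
  ts <- cfg$preprocess$target_spacing
  if (!is.null(ts)) {
    img <- resample_volume(img, ts, "linear")
    msk <- resample_volume(msk, ts, "nearest")
  }
  win <- apply_window(img, cfg$preprocess$window_level, cfg$preprocess$window_width)
  list(unit = vol_like(win, win$data / 255), mask = msk, id = cs$id)
}

aug_of <- function(cfg, stage, seed) {
  a <- cfg$augment[[stage]]
  augment_params(rotation_deg = a$rotation_deg, shift_x_px = a$shift_x_px,
                 shift_y_px = a$shift_y_px, zoom = a$zoom, seed = seed)
}

tc_of <- function(cfg, stage, aug_stage, seed) {
  tr <- cfg$train[[stage]]
  train_config(learning_rate = tr$learning_rate, batch_size = tr$batch_size,
               patience = tr$patience, max_epochs = tr$max_epochs,
               steps_per_epoch = tr$steps_per_epoch,
               augment = aug_of(cfg, aug_stage, seed), seed = seed)
}

#' Train the full segmentation pipeline from a phantom dataset
#'
#' Trains the coarse localization model on down-sampled axial slices of the
#' training split, selects its binarization threshold on the validation
#' split, crops every case to the cuboid ROI derived from the coarse
#' prediction, trains the three single-view models on the ROI slices, and
#' selects per-view and fusion thresholds on the validation split.
#' Deterministic given `cfg$seed`.
#'
#' @param data_dir dataset directory written by [generate_dataset()].
#' @param cfg configuration list, e.g. [desk_config()].
#' @param verbose log stage progress.
#' @return An object of class `mvseg_pipeline` bundling the four trained
#'   models, all selected thresholds and the configuration.
#' @export
train_pipeline <- function(data_dir, cfg = desk_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- read_manifest(data_dir)
  splits <- vapply(manifest$cases, function(cs) cs$split, character(1))
  train_cases <- manifest$cases[splits == "train"]
  val_cases <- manifest$cases[splits == "val"]
  if (length(train_cases) == 0 || length(val_cases) == 0)
    stop("manifest must contain train and val cases", call. = FALSE)

  say("loading %d train / %d val cases", length(train_cases), length(val_cases))
  tr <- lapply(train_cases, load_case, cfg = cfg)
  va <- lapply(val_cases, load_case, cfg = cfg)

  cf <- cfg$preprocess$coarse_factor
  wf <- cfg$preprocess$working_factor
  seed0 <- as.integer(cfg$seed)

  # ---- coarse stage --------------------------------------------------------
  coarse_slices <- function(cases) {
    imgs <- lapply(cases, function(cs)
      slice_views(downsample_inplane(cs$unit, cf))$axial$slices)
    msks <- lapply(cases, function(cs)
      slice_views(downsample_inplane(cs$mask, cf))$axial$slices)
    list(images = cat3(imgs), masks = cat3(msks))
  }
  tr_coarse <- coarse_slices(tr)
  va_coarse <- coarse_slices(va)
  hw <- dim(tr_coarse$images)[1:2]
  say("training coarse model on %d slices of %dx%d", dim(tr_coarse$images)[3],
      hw[1], hw[2])
  coarse_model <- build_model(seg_model_config(
    depth = cfg$model$depth, base_filters = cfg$model$base_filters,
    input_shape = hw, seed = seed0))
  coarse_model <- train(coarse_model, tr_coarse, va_coarse,
                        tc_of(cfg, "coarse", "coarse", seed0))

  va_coarse_prob <- lapply(va, function(cs)
    predict_stack(coarse_model, slice_views(downsample_inplane(cs$unit, cf))$axial))
  va_coarse_gt <- lapply(va, function(cs) downsample_inplane(cs$mask, cf))
  thr_coarse <- select_threshold(va_coarse_prob, va_coarse_gt, cfg$threshold_grid)
  say("coarse threshold: %.2f", thr_coarse)

  # ---- ROI extraction ------------------------------------------------------
  crop_case <- function(cs) {
    working <- downsample_inplane(cs$unit, wf)
    cmask <- tryCatch(
      coarse_localize(downsample_inplane(cs$unit, cf), coarse_model, thr_coarse),
      error = function(e) {
        # training-time fallback: centre the cuboid on the reference mask
        downsample_inplane(cs$mask, cf)
      })
    ext <- extract_roi(working, cmask, cfg$roi$size, inplane_scale = cf / wf)
    gt_roi <- roi_crop(downsample_inplane(cs$mask, wf), ext$roi)
    list(img = ext$volume, gt = gt_roi, roi = ext$roi, id = cs$id)
  }
  tr_roi <- lapply(tr, crop_case)
  va_roi <- lapply(va, crop_case)

  # ---- single-view stages --------------------------------------------------
  view_models <- list(); view_thr <- numeric(3)
  views <- c("axial", "sagittal", "coronal")
  va_prob <- list(axial = list(), sagittal = list(), coronal = list())
  for (k in seq_along(views)) {
    vw <- views[k]
    sl <- function(cases) list(
      images = cat3(lapply(cases, function(cs) slice_views(cs$img)[[vw]]$slices)),
      masks  = cat3(lapply(cases, function(cs) slice_views(cs$gt)[[vw]]$slices)))
    tr_sl <- sl(tr_roi); va_sl <- sl(va_roi)
    hw <- dim(tr_sl$images)[1:2]
    say("training %s model on %d slices of %dx%d", vw, dim(tr_sl$images)[3],
        hw[1], hw[2])
    m <- build_model(seg_model_config(
      depth = cfg$model$depth, base_filters = cfg$model$base_filters,
      input_shape = hw, seed = seed0 + k))
    m <- train(m, tr_sl, va_sl, tc_of(cfg, "view", vw, seed0 + k))
    view_models[[vw]] <- m
    va_prob[[vw]] <- lapply(va_roi, function(cs)
      smooth_stack(predict_stack(m, slice_views(cs$img)[[vw]]), vw, cfg$sigma))
    view_thr[k] <- select_threshold(va_prob[[vw]],
                                    lapply(va_roi, function(cs) cs$gt),
                                    cfg$threshold_grid)
    say("%s threshold: %.2f", vw, view_thr[k])
  }

  # ---- fusion thresholds ---------------------------------------------------
  va_gt <- lapply(va_roi, function(cs) cs$gt)
  fused_combined <- lapply(seq_along(va_roi), function(i)
    combined_fusion(list(va_prob$axial[[i]], va_prob$sagittal[[i]],
                         va_prob$coronal[[i]]), view_thr))
  thr_combined <- select_threshold(fused_combined, va_gt, cfg$threshold_grid)
  fused_avg <- lapply(seq_along(va_roi), function(i)
    average_probs(list(va_prob$axial[[i]], va_prob$sagittal[[i]],
                       va_prob$coronal[[i]])))
  thr_avg <- select_threshold(fused_avg, va_gt, cfg$threshold_grid)
  say("fusion thresholds: combined %.2f, average %.2f", thr_combined, thr_avg)

  structure(list(
    models = c(list(coarse = coarse_model), view_models),
    thresholds = list(coarse = thr_coarse, views = view_thr,
                      final_combined = thr_combined, final_average = thr_avg),
    cfg = cfg),
    class = "mvseg_pipeline")
}

#' @export
print.mvseg_pipeline <- function(x, ...) {
  cat("<mvseg_pipeline> coarse + axial/sagittal/coronal models\n")
  cat(sprintf("  thresholds: coarse %.2f, views (%.2f, %.2f, %.2f), combined %.2f, average %.2f\n",
              x$thresholds$coarse, x$thresholds$views[1], x$thresholds$views[2],
              x$thresholds$views[3], x$thresholds$final_combined,
              x$thresholds$final_average))
  invisible(x)
}

#' Segment a scan with a trained pipeline
#'
#' @param object a `mvseg_pipeline` from [train_pipeline()].
#' @param scan an intensity [volume()] in Hounsfield Units.
#' @param fusion fusion rule; defaults to the configured one.
#' @param ... passed to [run_pipeline()] (e.g. `verbose`).
#' @return A label [volume()] on the scan grid.
#' @export
predict.mvseg_pipeline <- function(object, scan, fusion = NULL, ...) {
  fusion <- fusion %||% object$cfg$fusion
  pp <- object$cfg$preprocess
  thr <- object$thresholds
  run_pipeline(scan, object$models,
               thresholds = list(coarse = thr$coarse, views = thr$views,
                                 final = if (fusion == "average")
                                   thr$final_average else thr$final_combined),
               fusion = fusion, sigma = object$cfg$sigma,
               window_level = pp$window_level, window_width = pp$window_width,
               target_spacing = pp$target_spacing,
               coarse_factor = pp$coarse_factor,
               working_factor = pp$working_factor,
               roi_size = object$cfg$roi$size, ...)
}

#' Evaluate a trained pipeline on a dataset split
#'
#' Segments every case of the chosen split and reports per-case Dice,
#' Jaccard and symmetric surface distances against ground truth.
#'
#' @param pipe a `mvseg_pipeline`.
#' @param data_dir dataset directory with a manifest.
#' @param split `"test"`, `"val"` or `"train"`.
#' @param fusion fusion rule; defaults to the configured one.
#' @param verbose log progress.
#' @return A `data.frame` with one [evaluate_case()] row per case.
#' @export
evaluate_pipeline <- function(pipe, data_dir, split = "test", fusion = NULL,
                              verbose = FALSE) {
  manifest <- read_manifest(data_dir)
  cases <- Filter(function(cs) cs$split == split, manifest$cases)
  if (length(cases) == 0) stop("no cases in split ", split, call. = FALSE)
  rows <- lapply(cases, function(cs) {
    scan <- read_volume(cs$image)
    gt <- read_volume(cs$mask, role = "label")
    pred <- predict(pipe, scan, fusion = fusion)
    if (verbose) message(cs$id, ": dsc ", round(dice(gt, pred), 3))
    evaluate_case(gt, pred, cs$id)
  })
  do.call(rbind, rows)
}

#' Per-view (unfused) evaluation of a trained pipeline
#'
#' Segments every case of a split with each single view alone (smoothed,
#' thresholded at that view's validated threshold, pasted back to the scan
#' grid) and with the coarse stage alone. Used to quantify what multi-view
#' fusion adds over single-plane segmentation.
#'
#' @inheritParams evaluate_pipeline
#' @return A `data.frame` with columns `case_id`, `view`, `dsc`.
#' @export
evaluate_single_views <- function(pipe, data_dir, split = "test") {
  manifest <- read_manifest(data_dir)
  cases <- Filter(function(cs) cs$split == split, manifest$cases)
  cfg <- pipe$cfg
  pp <- cfg$preprocess
  rows <- list()
  for (cs in cases) {
    scan <- read_volume(cs$image)
    gt <- read_volume(cs$mask, role = "label")
    win <- apply_window(if (is.null(pp$target_spacing)) scan else
      resample_volume(scan, pp$target_spacing, "linear"),
      pp$window_level, pp$window_width)
    unit <- vol_like(win, win$data / 255)
    working <- downsample_inplane(unit, pp$working_factor)
    coarse_in <- downsample_inplane(unit, pp$coarse_factor)
    cmask <- coarse_localize(coarse_in, pipe$models$coarse, pipe$thresholds$coarse)
    rows[[length(rows) + 1L]] <- data.frame(
      case_id = cs$id, view = "coarse",
      dsc = dice(downsample_inplane(gt, pp$coarse_factor), cmask))
    ext <- extract_roi(working, cmask, cfg$roi$size,
                       inplane_scale = pp$coarse_factor / pp$working_factor)
    views <- slice_views(ext$volume)
    for (k in seq_along(c("axial", "sagittal", "coronal"))) {
      vw <- c("axial", "sagittal", "coronal")[k]
      p <- smooth_stack(predict_stack(pipe$models[[vw]], views[[vw]]), vw, cfg$sigma)
      mask_roi <- binarize_volume(p, pipe$thresholds$views[k])
      full <- paste_roi(mask_roi, ext$roi, spacing = working$spacing,
                        origin = working$origin)
      pred <- resize_nearest(full, dim(scan$data), scan$spacing, scan$origin)
      rows[[length(rows) + 1L]] <- data.frame(case_id = cs$id, view = vw,
                                              dsc = dice(gt, pred))
    }
  }
  do.call(rbind, rows)
}
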