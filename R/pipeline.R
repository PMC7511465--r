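#' Decompose a volume into axial, sagittal and coronal view stacks
#'
#' Axial slices are taken at fixed z (shape `ny x nx`), coronal at fixed y
#' (`nz x nx`) and sagittal at fixed x (`nz x ny`). Each stack keeps enough
#' provenance to reassemble the source volume losslessly with
#' [reassemble_views()].
#'
#' @param v a [volume()].
#' @return `list(axial =, sagittal =, coronal =)` of `mvseg_view_stack`
#'   objects.
#' @export
slice_views <- function(v) {
  stop_if_not_volume(v)
  mk <- function(axis, slices) {
    structure(list(axis = axis, slices = slices, src_dim = dim(v$data),
                   spacing = v$spacing, origin = v$origin),
              class = "mvseg_view_stack")
  }
  list(axial    = mk("axial",    aperm(v$data, c(2, 3, 1))),
       sagittal = mk("sagittal", v$data),
       coronal  = mk("coronal",  aperm(v$data, c(1, 3, 2))))
}

#' Reassemble a view stack into a volume
#'
#' Exact inverse of [slice_views()] for the given axis.
#'
#' @param stack a `mvseg_view_stack`.
#' @param role role of the resulting [volume()].
#' @return A [volume()] on the stack's source grid.
#' @export
reassemble_views <- function(stack, role = "intensity") {
  if (!inherits(stack, "mvseg_view_stack"))
    stop("`stack` must come from slice_views()", call. = FALSE)
  data <- switch(stack$axis,
    axial    = aperm(stack$slices, c(3, 1, 2)),
    sagittal = stack$slices,
    coronal  = aperm(stack$slices, c(1, 3, 2)),
    stop("unknown view axis: ", stack$axis, call. = FALSE))
  volume(data, spacing = stack$spacing, origin = stack$origin, role = role)
}

#' Coarse localization of the vessel
#'
#' Runs the coarse model over the axial slices of a preprocessed,
#' in-plane down-sampled scan and binarizes the stacked probability map.
#'
#' @param scan an intensity [volume()], already windowed, scaled to unit
#'   range and down-sampled for the coarse stage.
#' @param coarse_model a trained [build_model()] whose input shape matches
#'   the axial slices of `scan`.
#' @param threshold binarization threshold in `(0, 1]`.
#' @return A label [volume()] on the coarse grid.
#' @export
coarse_localize <- function(scan, coarse_model, threshold) {
  stop_if_not_volume(scan)
  prob <- predict_stack(coarse_model, slice_views(scan)$axial)
  mask <- binarize_volume(prob, threshold)
  if (sum(mask$data) == 0)
    stop(sprintf("coarse localization found no foreground at threshold %.3g (max probability seen: %.4f)",
                 threshold, max(prob$data)), call. = FALSE)
  mask
}

#' Tight bounding box of a nonempty mask
#'
#' @param mask a label [volume()] or binary array.
#' @return `list(min =, max =)` of 1-based inclusive `(z, y, x)` voxel bounds.
#' @export
bounding_box <- function(mask) {
  m <- if (is_volume(mask)) mask$data else mask
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty; no bounding box", call. = FALSE)
  list(min = unname(apply(idx, 2, min)), max = unname(apply(idx, 2, max)))
}

#' Extract a fixed-size cuboid ROI centred on the coarse mask
#'
#' The cuboid centre is the centre of the coarse-mask bounding box, scaled
#' from the coarse grid to the working grid (in-plane only; the slice axis
#' is not down-sampled and maps 1:1). The crop has exactly `roi_size`
#' voxels, zero-padded wherever the cuboid exceeds the scan bounds, and the
#' returned ROI record allows results to be pasted back with [paste_roi()].
#'
#' @param scan_fine the working-resolution intensity [volume()].
#' @param coarse_mask nonempty label [volume()] from [coarse_localize()].
#' @param roi_size `(dz, dy, dx)` voxels; the full-scale default is
#'   `(480, 144, 144)`.
#' @param inplane_scale coarse-to-working in-plane coordinate scale
#'   (coarse factor / working factor; 2 for the default 4x / 2x factors).
#' @return `list(volume =, roi =)` where `roi` is a `mvseg_roi` record.
#' @export
extract_roi <- function(scan_fine, coarse_mask, roi_size = c(480, 144, 144),
                        inplane_scale = 2) {
  stop_if_not_volume(scan_fine)
  roi_size <- as.integer(roi_size)
  if (length(roi_size) != 3L || any(roi_size < 1L))
    stop("`roi_size` must be three positive voxel counts (dz, dy, dx)", call. = FALSE)
  bb <- bounding_box(coarse_mask)
  ctr_coarse <- (bb$min + bb$max) / 2
  scale <- c(1, inplane_scale, inplane_scale)
  ctr <- round((ctr_coarse - 0.5) * scale + 0.5)
  start <- as.integer(ctr - floor(roi_size / 2))
  d <- dim(scan_fine$data)
  crop <- array(0, roi_size)
  src_lo <- pmax(start, 1L); src_hi <- pmin(start + roi_size - 1L, d)
  if (any(src_lo > src_hi))
    stop("ROI lies entirely outside the scan", call. = FALSE)
  dst_lo <- src_lo - start + 1L; dst_hi <- src_hi - start + 1L
  crop[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    scan_fine$data[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  roi <- structure(list(start = start, size = roi_size, src_dim = d,
                        center = ctr, inplane_scale = inplane_scale),
                   class = "mvseg_roi")
  vol <- volume(crop, spacing = scan_fine$spacing,
                origin = scan_fine$origin + (start - 1L) * scan_fine$spacing,
                role = scan_fine$role)
  list(volume = vol, roi = roi)
}

#' Paste an ROI-sized mask back into full-scan coordinates
#'
#' Voxels outside the cuboid are background (0).
#'
#' @param mask_roi a label [volume()] of the ROI size.
#' @param roi the `mvseg_roi` record from [extract_roi()].
#' @param spacing,origin grid metadata of the full scan (defaults to the
#'   metadata implied by the ROI record and `mask_roi`).
#' @return A label [volume()] of the full working-scan size.
#' @export
paste_roi <- function(mask_roi, roi, spacing = mask_roi$spacing,
                      origin = mask_roi$origin - (roi$start - 1L) * mask_roi$spacing) {
  if (!inherits(roi, "mvseg_roi")) stop("`roi` must come from extract_roi()", call. = FALSE)
  if (!identical(dim(mask_roi$data), as.integer(roi$size)))
    stop("mask shape does not match the ROI record", call. = FALSE)
  full <- array(0, roi$src_dim)
  src_lo <- pmax(roi$start, 1L); src_hi <- pmin(roi$start + roi$size - 1L, roi$src_dim)
  dst_lo <- src_lo - roi$start + 1L; dst_hi <- src_hi - roi$start + 1L
  full[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]] <-
    mask_roi$data[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]]
  volume(full, spacing = spacing, origin = origin, role = mask_roi$role)
}

#' Smooth a probability stack along its stacking axis
#'
#' 1D Gaussian smoothing of the probability volume produced by a single
#' view, applied along the axis in which that view's 2D predictions are
#' independent (z for axial, y for coronal, x for sagittal). The kernel is
#' renormalized at the volume borders, so constant volumes are unchanged;
#' `sigma = 0` is the identity. Output is clipped to `[0, 1]`.
#'
#' @param prob a probability [volume()].
#' @param axis `"axial"`, `"coronal"` or `"sagittal"` (the view that
#'   produced `prob`), or `"z"`, `"y"`, `"x"` directly.
#' @param sigma Gaussian standard deviation in slices, >= 0.
#' @return A probability [volume()].
#' @export
smooth_stack <- function(prob, axis = "axial", sigma = 1) {
  stop_if_not_volume(prob)
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(prob)
  dim_ax <- switch(axis, axial = 1L, z = 1L, coronal = 2L, y = 2L,
                   sagittal = 3L, x = 3L,
                   stop("unknown axis: ", axis, call. = FALSE))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  off <- (-r):r
  kern <- exp(-off^2 / (2 * sigma^2))
  kern <- kern / sum(kern)

  perm <- c(dim_ax, setdiff(1:3, dim_ax))
  a <- aperm(prob$data, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  num <- matrix(0, d[1], ncol(m))
  den <- numeric(d[1])
  for (j in seq_along(off)) {
    src <- seq_len(d[1]) + off[j]
    ok <- src >= 1 & src <= d[1]
    num[ok, ] <- num[ok, ] + kern[j] * m[src[ok], , drop = FALSE]
    den[ok] <- den[ok] + kern[j]
  }
  out <- num / den
  out[out < 0] <- 0; out[out > 1] <- 1
  vol_like(prob, aperm(array(out, d), order(perm)), role = "probability")
}

fusion_check <- function(vols, n = 3L) {
  if (length(vols) != n) stop("exactly ", n, " volumes are required", call. = FALSE)
  for (v in vols) stop_if_not_volume(v)
  for (v in vols[-1]) check_same_shape(vols[[1]], v)
  invisible(TRUE)
}

#' Majority-vote fusion of three binary masks
#'
#' Each voxel takes the label held by at least two of the three view masks.
#' Permutation-invariant in its arguments.
#'
#' @param masks list of three shape-matched label [volume()]s.
#' @return A label [volume()].
#' @export
majority_vote <- function(masks) {
  fusion_check(masks)
  for (m in masks) if (!all(m$data %in% c(0, 1)))
    stop("majority voting requires binary masks", call. = FALSE)
  votes <- masks[[1]]$data + masks[[2]]$data + masks[[3]]$data
  vol_like(masks[[1]], (votes >= 2) * 1, role = "label")
}

#' Average fusion of three probability maps
#'
#' Per voxel, `p_final = (p_ax + p_sag + p_cor) / 3`.
#'
#' @param probs list of three shape-matched probability [volume()]s.
#' @return A probability [volume()].
#' @export
average_probs <- function(probs) {
  fusion_check(probs)
  vol_like(probs[[1]],
           (probs[[1]]$data + probs[[2]]$data + probs[[3]]$data) / 3,
           role = "probability")
}

#' Combined majority/averaging fusion
#'
#' Each view's probability map is binarized with its own validated
#' threshold. Where all three labels agree, the fused probability is set to
#' exactly 1 (foreground) or 0 (background); where they disagree, it is the
#' average of the three raw probabilities.
#'
#' @param probs list of three shape-matched probability [volume()]s in the
#'   order axial, sagittal, coronal.
#' @param view_thresholds numeric length-3 per-view thresholds in `(0, 1)`,
#'   same order.
#' @return A probability [volume()].
#' @export
combined_fusion <- function(probs, view_thresholds) {
  fusion_check(probs)
  if (length(view_thresholds) != 3L || any(view_thresholds <= 0 | view_thresholds >= 1))
    stop("`view_thresholds` must be three values in (0, 1)", call. = FALSE)
  l1 <- probs[[1]]$data >= view_thresholds[1]
  l2 <- probs[[2]]$data >= view_thresholds[2]
  l3 <- probs[[3]]$data >= view_thresholds[3]
  agree <- (l1 == l2) & (l2 == l3)
  avg <- (probs[[1]]$data + probs[[2]]$data + probs[[3]]$data) / 3
  out <- ifelse(agree, l1 * 1, avg)
  vol_like(probs[[1]], array(out, dim(avg)), role = "probability")
}

# Nearest-neighbour resize of a volume onto an explicit target grid
# (used to carry the fused working-resolution mask back to the scan grid).
resize_nearest <- function(v, target_dim, target_spacing, target_origin = v$origin) {
  arr <- v$data
  for (ax in 1:3) {
    if (dim(arr)[ax] == target_dim[ax]) next
    # voxel-centre mapping between grids of different size
    n_in <- dim(arr)[ax]; n_out <- target_dim[ax]
    x <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
    idx <- pmin(pmax(floor(x + 0.5), 0), n_in - 1) + 1
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])[idx, , drop = FALSE]
    arr <- aperm(array(m, c(n_out, d[2], d[3])), order(perm))
  }
  volume(arr, spacing = target_spacing, origin = target_origin, role = v$role)
}

#' Run the full coarse-to-fine multi-view segmentation pipeline
#'
#' Preprocesses the scan (optional resampling, Hounsfield windowing, unit
#' scaling), localizes the vessel on strongly down-sampled axial slices,
#' crops the fixed-size cuboid ROI at working resolution, segments it from
#' the three orthogonal views, smooths each probability stack along its
#' stacking axis, fuses the views, binarizes, and pastes the mask back onto
#' the input scan grid.
#'
#' @param scan an intensity [volume()] in Hounsfield Units.
#' @param models `list(coarse =, axial =, sagittal =, coronal =)` of trained
#'   [build_model()] objects.
#' @param thresholds `list(coarse =, views = c(axial, sagittal, coronal),
#'   final =)` of validated binarization thresholds.
#' @param fusion `"majority"`, `"average"` or `"combined"`.
#' @param sigma Gaussian stack-smoothing standard deviation in slices.
#' @param window_level,window_width Hounsfield window (default 200/800).
#' @param target_spacing optional `(sz, sy, sx)` mm resampling target;
#'   `NULL` keeps the input grid.
#' @param coarse_factor,working_factor in-plane down-sampling factors for
#'   the localization and segmentation stages (defaults 4 and 2).
#' @param roi_size cuboid `(dz, dy, dx)` in working-grid voxels.
#' @param verbose log each stage via `message()`.
#' @return A label [volume()] on the input scan grid.
#' @export
run_pipeline <- function(scan, models, thresholds, fusion = c("combined", "majority", "average"),
                         sigma = 1, window_level = 200, window_width = 800,
                         target_spacing = NULL, coarse_factor = 4L,
                         working_factor = 2L, roi_size = c(480, 144, 144),
                         verbose = FALSE) {
  fusion <- match.arg(fusion)
  stop_if_not_volume(scan)
  say <- function(...) if (verbose) message(sprintf(...))
  for (nm in c("coarse", "axial", "sagittal", "coronal"))
    if (!inherits(models[[nm]], "mvseg_model"))
      stop("`models$", nm, "` must be a trained mvseg_model", call. = FALSE)

  pre <- scan
  if (!is.null(target_spacing)) {
    say("resampling to (%.3g, %.3g, %.3g) mm", target_spacing[1],
        target_spacing[2], target_spacing[3])
    pre <- resample_volume(pre, target_spacing, "linear")
  }
  say("windowing at level %g width %g HU", window_level, window_width)
  win <- apply_window(pre, window_level, window_width)
  unit <- vol_like(win, win$data / 255)

  working <- downsample_inplane(unit, working_factor)
  coarse_in <- downsample_inplane(unit, coarse_factor)
  say("coarse localization on %s grid", paste(dim(coarse_in$data), collapse = "x"))
  cmask <- coarse_localize(coarse_in, models$coarse, thresholds$coarse)

  ext <- extract_roi(working, cmask, roi_size,
                     inplane_scale = coarse_factor / working_factor)
  say("ROI at (%s), size (%s)", paste(ext$roi$center, collapse = ", "),
      paste(ext$roi$size, collapse = ", "))

  views <- slice_views(ext$volume)
  probs <- list(
    axial    = smooth_stack(predict_stack(models$axial, views$axial), "axial", sigma),
    sagittal = smooth_stack(predict_stack(models$sagittal, views$sagittal), "sagittal", sigma),
    coronal  = smooth_stack(predict_stack(models$coronal, views$coronal), "coronal", sigma))
  say("fusing views (%s)", fusion)
  fused_mask <- switch(fusion,
    majority = majority_vote(list(
      binarize_volume(probs$axial, thresholds$views[1]),
      binarize_volume(probs$sagittal, thresholds$views[2]),
      binarize_volume(probs$coronal, thresholds$views[3]))),
    average  = binarize_volume(average_probs(unname(probs)), thresholds$final),
    combined = binarize_volume(
      combined_fusion(unname(probs), thresholds$views), thresholds$final))

  full_working <- paste_roi(fused_mask, ext$roi, spacing = working$spacing,
                            origin = working$origin)
  out <- resize_nearest(full_working, dim(scan$data), scan$spacing, scan$origin)
  say("final mask: %d foreground voxels", sum(out$data))
  out
}
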