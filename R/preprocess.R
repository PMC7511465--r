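#' Resample a volume to a target voxel spacing
#'
#' Separable per-axis resampling on voxel centres. The number of output
#' voxels per axis is `round(n_old * old_spacing / new_spacing)`, which
#' preserves the physical extent of the volume to within one output voxel.
#' Label volumes are always resampled with nearest-neighbour interpolation
#' and therefore stay binary.
#'
#' @param v a [volume()].
#' @param target_spacing numeric length-3 `(sz, sy, sx)` in mm, all > 0.
#' @param interp `"linear"` (default for intensity/probability) or
#'   `"nearest"`. Ignored for label volumes, which force `"nearest"`.
#' @return A [volume()] with `spacing == target_spacing`.
#' @export
resample_volume <- function(v, target_spacing, interp = c("linear", "nearest")) {
  stop_if_not_volume(v)
  interp <- match.arg(interp)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("`target_spacing` must be three strictly positive values (mm)", call. = FALSE)
  if (v$role == "label") interp <- "nearest"
  if (isTRUE(all.equal(v$spacing, target_spacing, tolerance = 1e-12))) return(v)
  arr <- v$data
  for (ax in 1:3) {
    if (abs(v$spacing[ax] - target_spacing[ax]) < 1e-12) next
    n_out <- max(1L, as.integer(round(dim(arr)[ax] * v$spacing[ax] / target_spacing[ax])))
    arr <- resample_axis(arr, ax, v$spacing[ax], target_spacing[ax], n_out, interp)
  }
  vol_like(v, arr, spacing = target_spacing)
}

# 1D resampling of one array axis at voxel centres.
resample_axis <- function(arr, axis, old_sp, new_sp, n_out, interp) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  x <- ((seq_len(n_out) - 0.5) * new_sp / old_sp) - 0.5   # 0-based source coords
  if (interp == "nearest") {
    idx <- pmin(pmax(floor(x + 0.5), 0), d[1] - 1) + 1
    out <- m[idx, , drop = FALSE]
  } else {
    i0 <- floor(x)
    w <- x - i0
    lo <- pmin(pmax(i0, 0), d[1] - 1) + 1
    hi <- pmin(pmax(i0 + 1, 0), d[1] - 1) + 1
    out <- m[lo, , drop = FALSE] * (1 - w) + m[hi, , drop = FALSE] * w
  }
  aperm(array(out, c(n_out, d[2], d[3])), order(perm))
}

#' Apply a Hounsfield window
#'
#' Linearly maps the HU interval `[level - width/2, level + width/2]` onto
#' `[0, 255]`, clamping outside. The default 200/800 window maps
#' `[-200, 600]` HU to the display range, which brackets contrast-enhanced
#' lumen while saturating air and dense bone.
#'
#' @param v an intensity [volume()] in Hounsfield Units.
#' @param level window centre in HU.
#' @param width window width in HU, > 0.
#' @return An intensity [volume()] with values in `[0, 255]`.
#' @export
apply_window <- function(v, level = 200, width = 800) {
  stop_if_not_volume(v)
  if (v$role != "intensity")
    stop("windowing applies to intensity volumes, got role ", v$role, call. = FALSE)
  if (!is.finite(width) || width <= 0) stop("`width` must be > 0", call. = FALSE)
  lo <- level - width / 2
  out <- (v$data - lo) / width
  out[out < 0] <- 0
  out[out > 1] <- 1
  vol_like(v, out * 255)
}

#' Down-sample a volume in-plane
#'
#' Reduces the axial in-plane (y, x) resolution by an integer factor;
#' the slice axis z is untouched. Intensity and probability volumes are
#' block-averaged when the in-plane dimensions are divisible by the factor
#' (and linearly resampled otherwise); label volumes use nearest-neighbour
#' sampling and stay binary. In-plane spacing is multiplied by the factor.
#'
#' @param v a [volume()].
#' @param factor integer >= 1; 1 is the identity.
#' @return A [volume()] with in-plane dimensions divided by `factor` (rounded).
#' @export
downsample_inplane <- function(v, factor) {
  stop_if_not_volume(v)
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a single integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(v)
  d <- dim(v$data)
  new_spacing <- v$spacing * c(1, factor, factor)
  divisible <- all(d[2:3] %% factor == 0L)
  if (v$role != "label" && divisible) {
    arr <- block_mean_axis(v$data, 2L, factor)
    arr <- block_mean_axis(arr, 3L, factor)
    return(vol_like(v, arr, spacing = new_spacing))
  }
  interp <- if (v$role == "label") "nearest" else "linear"
  arr <- v$data
  for (ax in 2:3) {
    n_out <- max(1L, as.integer(round(d[ax] / factor)))
    arr <- resample_axis(arr, ax, v$spacing[ax], new_spacing[ax], n_out, interp)
  }
  vol_like(v, arr, spacing = new_spacing)
}

block_mean_axis <- function(arr, axis, f) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  blocks <- array(a, c(f, d[1] %/% f, d[2], d[3]))
  m <- colMeans(blocks)                      # (n/f, d2, d3)
  aperm(m, order(perm))
}

#' Slice-level augmentation parameters
#'
#' Closed intervals from which one rotation angle, shift vector and zoom
#' factor are drawn uniformly per augmented slice pair. The defaults are the
#' ranges used for coarse-stage training: rotations within +/- 10 degrees,
#' width (x) shifts within +/- 20 px, height (y) shifts within +/- 22 px and
#' zoom factors in `[0.85, 1.15]`. The finer single-view stages use +/- 7
#' degree rotations, +/- 22 px width shifts, and +/- 22 px (axial) or
#' +/- 72 px (sagittal/coronal) height shifts.
#'
#' @param rotation_deg length-2 interval of rotation angles (degrees).
#' @param shift_x_px length-2 interval of column shifts (pixels).
#' @param shift_y_px length-2 interval of row shifts (pixels).
#' @param zoom length-2 strictly positive interval of zoom factors.
#' @param seed integer seed making the draw deterministic.
#' @return An object of class `mvseg_augment`.
#' @export
augment_params <- function(rotation_deg = c(-10, 10), shift_x_px = c(-20, 20),
                           shift_y_px = c(-22, 22), zoom = c(0.85, 1.15),
                           seed = 0L) {
  chk <- function(iv, nm) {
    if (length(iv) != 2L || any(!is.finite(iv)) || iv[1] > iv[2])
      stop("`", nm, "` must be a closed interval lo <= hi", call. = FALSE)
  }
  chk(rotation_deg, "rotation_deg"); chk(shift_x_px, "shift_x_px")
  chk(shift_y_px, "shift_y_px"); chk(zoom, "zoom")
  if (zoom[1] <= 0) stop("`zoom` interval must be strictly positive", call. = FALSE)
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 shift_x_px = as.numeric(shift_x_px),
                 shift_y_px = as.numeric(shift_y_px),
                 zoom = as.numeric(zoom), seed = as.integer(seed)),
            class = "mvseg_augment")
}

#' Jointly augment an image/mask slice pair
#'
#' Draws one rotation angle, shift vector and zoom factor uniformly from the
#' intervals in `params` (deterministically given `params$seed`) and applies
#' the same spatial transform to both slices: bilinear interpolation for the
#' image, nearest-neighbour for the mask, zero fill outside the source.
#' The mask output therefore remains binary.
#'
#' @param image numeric matrix.
#' @param mask numeric matrix of the same shape with values in `{0, 1}`.
#' @param params an [augment_params()] object.
#' @return `list(image =, mask =)` of transformed matrices.
#' @export
augment_pair <- function(image, mask, params) {
  if (!is.matrix(image) || !is.matrix(mask) || !identical(dim(image), dim(mask)))
    stop("`image` and `mask` must be matrices of identical shape", call. = FALSE)
  if (!inherits(params, "mvseg_augment"))
    stop("`params` must come from augment_params()", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(params$seed)
  theta <- stats::runif(1, params$rotation_deg[1], params$rotation_deg[2]) * pi / 180
  sx <- stats::runif(1, params$shift_x_px[1], params$shift_x_px[2])
  sy <- stats::runif(1, params$shift_y_px[1], params$shift_y_px[2])
  zf <- stats::runif(1, params$zoom[1], params$zoom[2])
  warp_pair(image, mask, theta, sx, sy, zf)
}

# Shared inverse-mapped affine warp (rotate about centre, zoom, then shift).
warp_pair <- function(image, mask, theta, sx, sy, zf) {
  nr <- nrow(image); nc <- ncol(image)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r <- matrix(seq_len(nr), nr, nc) - cr - sy
  c <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cc - sx
  ct <- cos(theta); st <- sin(theta)
  src_r <- ( ct * r + st * c) / zf + cr
  src_c <- (-st * r + ct * c) / zf + cc
  list(image = bilinear_sample(image, src_r, src_c),
       mask = nearest_sample(mask, src_r, src_c))
}

bilinear_sample <- function(img, rs, cs, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  inside <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
  r0 <- pmin(pmax(floor(rs), 1), nr); c0 <- pmin(pmax(floor(cs), 1), nc)
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  wr <- pmin(pmax(rs - r0, 0), 1); wc <- pmin(pmax(cs - c0, 0), 1)
  v <- img[cbind(c(r0), c(c0))] * (1 - wr) * (1 - wc) +
       img[cbind(c(r1), c(c0))] * wr * (1 - wc) +
       img[cbind(c(r0), c(c1))] * (1 - wr) * wc +
       img[cbind(c(r1), c(c1))] * wr * wc
  out <- matrix(fill, nr, nc)
  out[inside] <- v[inside]
  out
}

nearest_sample <- function(img, rs, cs, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- floor(rs + 0.5); ci <- floor(cs + 0.5)
  inside <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  out <- matrix(fill, nr, nc)
  out[inside] <- img[cbind(ri[inside], ci[inside])]
  out
}
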