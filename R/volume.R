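#' Volumetric image container
#'
#' A `mvseg_volume` holds a 3D voxel grid together with its physical
#' metadata. The package-wide axis convention is `(z, y, x)`: `data[k, , ]`
#' is the k-th axial slice, `data[, j, ]` the j-th coronal slice and
#' `data[, , i]` the i-th sagittal slice. Spacing and origin are stored in
#' millimetres in the same axis order.
#'
#' @param data numeric 3D array indexed `(z, y, x)`.
#' @param spacing numeric length-3, voxel size in mm `(sz, sy, sx)`; all > 0.
#' @param origin numeric length-3, position of the first voxel centre in mm.
#' @param role one of `"intensity"` (Hounsfield Units or windowed grey
#'   values), `"probability"` (values in `[0, 1]`) or `"label"`
#'   (values in `{0, 1}`).
#'
#' @return An object of class `mvseg_volume`.
#' @examples
#' v <- volume(array(0, c(4, 5, 6)), spacing = c(1, 0.73, 0.73))
#' dim(v)
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   role = c("intensity", "probability", "label")) {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)", call. = FALSE)
  if (any(dim(data) < 1L)) stop("`data` must be non-empty on all three axes", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  storage.mode(data) <- "double"
  v <- structure(list(data = data, spacing = spacing, origin = origin, role = role),
                 class = "mvseg_volume")
  validate_volume(v)
  v
}

validate_volume <- function(v) {
  if (v$role == "probability") {
    r <- range(v$data)
    if (r[1] < 0 || r[2] > 1)
      stop("probability volume has values outside [0, 1]", call. = FALSE)
  }
  if (v$role == "label" && !all(v$data %in% c(0, 1)))
    stop("label volume has values outside {0, 1}", call. = FALSE)
  invisible(v)
}

#' @export
dim.mvseg_volume <- function(x) dim(x$data)

#' @export
print.mvseg_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mvseg_volume> %s  %d x %d x %d voxels (z, y, x)\n",
              x$role, d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.4g x %.4g x %.4g mm, origin: (%.4g, %.4g, %.4g) mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  value range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

# Shallow constructor reusing metadata of `v`.
vol_like <- function(v, data, role = v$role, spacing = v$spacing, origin = v$origin) {
  volume(data, spacing = spacing, origin = origin, role = role)
}

is_volume <- function(x) inherits(x, "mvseg_volume")

stop_if_not_volume <- function(x, arg = deparse(substitute(x))) {
  if (!is_volume(x)) stop(sprintf("`%s` must be a mvseg_volume", arg), call. = FALSE)
  invisible(x)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes are not shape-matched: ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}
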