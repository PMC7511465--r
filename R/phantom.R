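#' Synthetic vascular phantom specification
#'
#' Describes a contrast-enhanced tubular phantom: a bright lumen swept along
#' a smooth centreline inside a darker background, with optional aneurysmal
#' bulge, branch vessels, bright distractor blobs disjoint from the lumen
#' (emulating confounders such as prosthesis artifacts and neighbouring
#' vessels), and additive Gaussian noise. Default intensities put the lumen
#' in the 250-450 HU contrast band and the background in soft-tissue range,
#' so the standard 200/800 HU window is exercised meaningfully.
#'
#' @param shape grid size `(nz, ny, nx)` in voxels.
#' @param spacing voxel spacing `(sz, sy, sx)` in mm.
#' @param centerline_ctrl_points numeric matrix (>= 4 rows) of `(z, y, x)`
#'   control points in voxel coordinates; a smooth curve is interpolated
#'   through them. `NULL` uses a gently curved near-vertical default.
#' @param radius_profile lumen radius in mm at each control point (recycled
#'   if length 1); all > 0.
#' @param aneurysm `NULL` or `list(center_frac =, bulge =)`: a focal
#'   dilatation at the given fraction along the centreline with radius
#'   multiplier `bulge >= 1`.
#' @param branches list of `list(attach_frac, direction, length_mm,
#'   radius_mm)` branch tubes; `attach_frac` in `[0, 1]`, `direction` a
#'   `(z, y, x)` vector (normalised internally, mm space).
#' @param lumen_hu,background_hu HU intervals for lumen and background.
#' @param distractors number of bright non-lumen blobs.
#' @param noise_sd additive Gaussian noise standard deviation, HU, >= 0.
#' @param seed integer seed; phantoms are bit-reproducible given the spec.
#' @return An object of class `mvseg_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 96, 96), spacing = c(1, 1, 1),
                         centerline_ctrl_points = NULL, radius_profile = 9,
                         aneurysm = list(center_frac = 0.55, bulge = 1.7),
                         branches = list(), lumen_hu = c(250, 450),
                         background_hu = c(-50, 80), distractors = 3,
                         noise_sd = 20, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(spacing) == 3L, all(spacing > 0))
  if (is.null(centerline_ctrl_points)) {
    zf <- seq(0.12, 0.88, length.out = 6)
    centerline_ctrl_points <- cbind(
      z = zf * (shape[1] - 1) + 1,
      y = shape[2] / 2 + 8 * sin(zf * pi * 1.5),
      x = shape[3] / 2 + 6 * cos(zf * pi))
  }
  cp <- as.matrix(centerline_ctrl_points)
  if (nrow(cp) < 4L || ncol(cp) != 3L)
    stop("`centerline_ctrl_points` needs >= 4 (z, y, x) points", call. = FALSE)
  radius_profile <- rep_len(as.numeric(radius_profile), nrow(cp))
  if (any(radius_profile <= 0)) stop("radii must be positive", call. = FALSE)
  if (!is.null(aneurysm)) {
    stopifnot(is.list(aneurysm), aneurysm$bulge >= 1,
              aneurysm$center_frac >= 0, aneurysm$center_frac <= 1)
  }
  for (br in branches) {
    stopifnot(br$attach_frac >= 0, br$attach_frac <= 1,
              br$length_mm > 0, br$radius_mm > 0, length(br$direction) == 3L)
  }
  stopifnot(noise_sd >= 0, distractors >= 0,
            lumen_hu[1] <= lumen_hu[2], background_hu[1] <= background_hu[2])
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 centerline_ctrl_points = cp, radius_profile = radius_profile,
                 aneurysm = aneurysm, branches = branches,
                 lumen_hu = as.numeric(lumen_hu),
                 background_hu = as.numeric(background_hu),
                 distractors = as.integer(distractors),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "mvseg_phantom_spec")
}

#' Generate a synthetic vascular phantom
#'
#' Builds the ground-truth lumen mask by sweeping spheres along a cubic
#' spline through the centreline control points (sampled at <= 0.5 voxel
#' steps), adding branch tubes and the aneurysmal bulge, then paints the
#' intensity volume: per-voxel uniform draws from the lumen interval inside
#' the mask, from the background interval outside, bright distractor blobs
#' strictly disjoint from the lumen, and additive Gaussian noise.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return `list(image = intensity volume, label = label volume)`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "mvseg_phantom_spec"))
    stop("`spec` must come from phantom_spec()", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  d <- spec$shape
  sp <- spec$spacing
  label <- array(FALSE, d)

  cl <- sample_centerline(spec$centerline_ctrl_points, spec$radius_profile,
                          sp, step_vox = 0.4)
  r <- cl$radius
  if (!is.null(spec$aneurysm)) {
    an <- spec$aneurysm
    r <- r * (1 + (an$bulge - 1) * exp(-((cl$frac - an$center_frac) / 0.08)^2))
  }
  label <- stamp_tube(label, cl$points, r, sp, clip = FALSE,
                      what = "main tube")

  for (br in spec$branches) {
    p0 <- spline_point(spec$centerline_ctrl_points, br$attach_frac)
    dir_mm <- as.numeric(br$direction)
    dir_mm <- dir_mm / sqrt(sum(dir_mm^2))
    n_step <- max(2L, ceiling(br$length_mm / (0.4 * min(sp))))
    tt <- seq(0, br$length_mm, length.out = n_step)
    pts <- t(vapply(tt, function(s) p0 + s * dir_mm / sp, numeric(3)))
    label <- stamp_tube(label, pts, rep(br$radius_mm, n_step), sp,
                        clip = FALSE, what = "branch")
  }

  n <- prod(d)
  img <- array(stats::runif(n, spec$background_hu[1], spec$background_hu[2]), d)
  nl <- sum(label)
  img[label] <- stats::runif(nl, spec$lumen_hu[1], spec$lumen_hu[2])

  if (spec$distractors > 0) {
    dist_to_lumen <- sqrt(cpp_edt_sq(label * 1, sp))
    placed <- 0L
    tries <- 0L
    while (placed < spec$distractors && tries < 500L) {
      tries <- tries + 1L
      rb <- stats::runif(1, 3, 8)
      ctr <- c(stats::runif(1, 2, d[1] - 1), stats::runif(1, 2, d[2] - 1),
               stats::runif(1, 2, d[3] - 1))
      if (dist_to_lumen[matrix(round(ctr), 1)] <= rb + 2) next
      blob <- sphere_voxels(d, ctr, rb, sp)
      blob <- blob & !label
      img[blob] <- stats::runif(sum(blob), spec$lumen_hu[1], spec$lumen_hu[2])
      placed <- placed + 1L
    }
  }

  if (spec$noise_sd > 0) img <- img + stats::rnorm(n, 0, spec$noise_sd)

  list(image = volume(img, spacing = sp, role = "intensity"),
       label = volume(label * 1, spacing = sp, role = "label"))
}

# Cubic-spline centreline sampled densely in arc length; returns voxel-space
# points, per-sample radius (mm) and the arc-length fraction of each sample.
sample_centerline <- function(cp, radius_profile, spacing, step_vox = 0.4) {
  tt <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  tt <- tt / tt[length(tt)]
  fz <- stats::splinefun(tt, cp[, 1], method = "natural")
  fy <- stats::splinefun(tt, cp[, 2], method = "natural")
  fx <- stats::splinefun(tt, cp[, 3], method = "natural")
  fr <- stats::approxfun(tt, radius_profile, rule = 2)
  # estimate curve length in voxel units to choose the sample count
  probe <- seq(0, 1, length.out = 200)
  pl <- sum(sqrt(rowSums(diff(cbind(fz(probe), fy(probe), fx(probe)))^2)))
  ns <- max(4L, ceiling(pl / step_vox))
  s <- seq(0, 1, length.out = ns)
  list(points = cbind(fz(s), fy(s), fx(s)), radius = fr(s), frac = s)
}

spline_point <- function(cp, frac) {
  tt <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  tt <- tt / tt[length(tt)]
  c(stats::splinefun(tt, cp[, 1], method = "natural")(frac),
    stats::splinefun(tt, cp[, 2], method = "natural")(frac),
    stats::splinefun(tt, cp[, 3], method = "natural")(frac))
}

# Union of spheres centred at `pts` (voxel coords) with radii `r` (mm).
stamp_tube <- function(label, pts, r, spacing, clip = FALSE, what = "tube") {
  d <- dim(label)
  for (i in seq_len(nrow(pts))) {
    rv <- r[i] / spacing                      # radius in voxels per axis
    lo <- floor(pts[i, ] - rv); hi <- ceiling(pts[i, ] + rv)
    if (!clip && (any(lo < 1) || any(hi > d)))
      stop(sprintf("%s exceeds volume bounds at voxel (%.1f, %.1f, %.1f) with radius %.1f mm; enlarge `shape` or shrink the tube",
                   what, pts[i, 1], pts[i, 2], pts[i, 3], r[i]), call. = FALSE)
    lo <- pmax(lo, 1); hi <- pmin(hi, d)
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    dz2 <- ((iz - pts[i, 1]) * spacing[1])^2
    dy2 <- ((iy - pts[i, 2]) * spacing[2])^2
    dx2 <- ((ix - pts[i, 3]) * spacing[3])^2
    inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r[i]^2
    label[iz, iy, ix] <- label[iz, iy, ix] | inside
  }
  label
}

sphere_voxels <- function(d, ctr, r_mm, spacing) {
  out <- array(FALSE, d)
  rv <- r_mm / spacing
  lo <- pmax(floor(ctr - rv), 1); hi <- pmin(ceiling(ctr + rv), d)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  dz2 <- ((iz - ctr[1]) * spacing[1])^2
  dy2 <- ((iy - ctr[2]) * spacing[2])^2
  dx2 <- ((ix - ctr[3]) * spacing[3])^2
  out[iz, iy, ix] <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r_mm^2
  out
}

#' Generate a phantom dataset with train/validation/test splits
#'
#' Writes `n_train + n_val + n_test` image/mask NIfTI pairs with per-case
#' randomized centreline curvature, lumen radius, aneurysm presence and
#' branches, plus a JSON manifest recording split membership and per-case
#' seeds. Fully reproducible from `seed`.
#'
#' @param n_train,n_val,n_test case counts per split, all >= 1.
#' @param out_dir output directory (must exist or be creatable).
#' @param base_spec template [phantom_spec()]; per-case geometry is
#'   randomized around it, intensities and noise are taken from it.
#' @param seed integer master seed.
#' @return The manifest as a list (invisibly); also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
generate_dataset <- function(n_train, n_val, n_test, out_dir,
                             base_spec = phantom_spec(), seed = 1L) {
  stopifnot(n_train >= 1, n_val >= 1, n_test >= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  n_all <- n_train + n_val + n_test
  split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  d <- base_spec$shape
  cases <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    amp_y <- stats::runif(1, 4, 12)
    amp_x <- stats::runif(1, 3, 9)
    phase <- stats::runif(2, 0, 2 * pi)
    radius <- stats::runif(1, 7, 11)
    has_an <- stats::runif(1) < 0.6
    an <- if (has_an) list(center_frac = stats::runif(1, 0.35, 0.7),
                           bulge = stats::runif(1, 1.4, 2.0)) else NULL
    n_br <- sample(0:2, 1)
    branches <- lapply(seq_len(n_br), function(j) {
      ang <- stats::runif(1, 0, 2 * pi)
      list(attach_frac = stats::runif(1, 0.25, 0.75),
           direction = c(stats::runif(1, -0.4, 0.4), sin(ang), cos(ang)),
           length_mm = stats::runif(1, 10, 18),
           radius_mm = stats::runif(1, 2.5, 4))
    })
    zf <- seq(0.12, 0.88, length.out = 6)
    cp <- cbind(z = zf * (d[1] - 1) + 1,
                y = d[2] / 2 + amp_y * sin(zf * pi * 1.5 + phase[1]),
                x = d[3] / 2 + amp_x * cos(zf * pi + phase[2]))
    case_seed <- (seed * 10007L + i * 101L) %% 2147483647L
    spec_i <- phantom_spec(shape = d, spacing = base_spec$spacing,
                           centerline_ctrl_points = cp,
                           radius_profile = radius, aneurysm = an,
                           branches = branches,
                           lumen_hu = base_spec$lumen_hu,
                           background_hu = base_spec$background_hu,
                           distractors = base_spec$distractors,
                           noise_sd = base_spec$noise_sd, seed = case_seed)
    ph <- generate_phantom(spec_i)
    id <- sprintf("case_%02d", i)
    img_path <- file.path(out_dir, paste0(id, "_img.nii.gz"))
    msk_path <- file.path(out_dir, paste0(id, "_mask.nii.gz"))
    write_volume(ph$image, img_path, datatype = "float")
    write_volume(ph$label, msk_path)
    cases[[i]] <- list(id = id, split = split[i], image = basename(img_path),
                       mask = basename(msk_path), seed = case_seed,
                       radius_mm = radius, aneurysm = has_an,
                       n_branches = n_br)
  }
  manifest <- list(seed = seed, shape = d, spacing = base_spec$spacing,
                   n_train = n_train, n_val = n_val, n_test = n_test,
                   cases = cases)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset manifest written by [generate_dataset()]
#' @param dir dataset directory containing `manifest.json`.
#' @return The manifest list with absolute image/mask paths attached.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir, call. = FALSE)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$cases <- lapply(m$cases, function(cs) {
    cs$image <- file.path(dir, cs$image)
    cs$mask <- file.path(dir, cs$mask)
    cs
  })
  m
}
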