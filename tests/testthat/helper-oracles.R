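# Shared fixtures and independent brute-force oracles used across the suite.

# Binary label volume from an array (or dims + foreground probability).
random_mask_vol <- function(dims, p = 0.3, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  volume(array(rbinom(prod(dims), 1, p), dims) * 1, spacing = spacing,
         role = "label")
}

label_vol <- function(arr, spacing = c(1, 1, 1)) {
  volume(arr * 1, spacing = spacing, role = "label")
}

prob_vol <- function(arr, spacing = c(1, 1, 1)) {
  volume(arr, spacing = spacing, role = "probability")
}

# Set-count overlap oracles on voxel index sets (independent of the
# array-arithmetic implementation).
bf_dice <- function(a, b) {
  sa <- which(a > 0); sb <- which(b > 0)
  if (length(sa) + length(sb) == 0) return(1)
  2 * length(intersect(sa, sb)) / (length(sa) + length(sb))
}

bf_jaccard <- function(a, b) {
  sa <- which(a > 0); sb <- which(b > 0)
  u <- length(union(sa, sb))
  if (u == 0) return(1)
  length(intersect(sa, sb)) / u
}

# O(n^2) all-pairs symmetric surface distances. Boundary voxels are found by
# an explicit per-voxel 6-neighbour loop; distances by exhaustive pairwise
# physical-coordinate search.
bf_boundary <- function(m) {
  d <- dim(m)
  out <- matrix(0, nrow = 0, ncol = 3)
  for (k in seq_len(d[1])) for (j in seq_len(d[2])) for (i in seq_len(d[3])) {
    if (m[k, j, i] == 0) next
    nb_bg <- FALSE
    for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
      q <- c(k, j, i) + off
      if (any(q < 1) || any(q > d) || m[q[1], q[2], q[3]] == 0) {
        nb_bg <- TRUE
        break
      }
    }
    if (nb_bg) out <- rbind(out, c(k, j, i))
  }
  out
}

bf_surface_distances <- function(a, b, spacing = c(1, 1, 1)) {
  pa <- bf_boundary(a); pb <- bf_boundary(b)
  pa_mm <- sweep(pa, 2, spacing, `*`); pb_mm <- sweep(pb, 2, spacing, `*`)
  one_way <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      sqrt(min(colSums((t(q) - p[i, ])^2))), numeric(1))
  }
  d <- c(one_way(pa_mm, pb_mm), one_way(pb_mm, pa_mm))
  list(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0, max = max(d))
}

# Direct "same" zero-padded 2D convolution oracle (naive loops).
bf_conv2d <- function(x, w, bias) {
  dx <- dim(x); dw <- dim(w)
  H <- dx[1]; W <- dx[2]; Cin <- dx[3]; B <- dx[4]
  k <- dw[1]; Cout <- dw[4]; p <- (k - 1) / 2
  y <- array(0, c(H, W, Cout, B))
  for (bimg in 1:B) for (co in 1:Cout) for (wc in 1:W) for (hc in 1:H) {
    acc <- bias[co]
    for (ci in 1:Cin) for (b in 1:k) for (a in 1:k) {
      sh <- hc + a - 1 - p; sw <- wc + b - 1 - p
      if (sh >= 1 && sh <= H && sw >= 1 && sw <= W)
        acc <- acc + x[sh, sw, ci, bimg] * w[a, b, ci, co]
    }
    y[hc, wc, co, bimg] <- acc
  }
  y
}

# Brute-force squared EDT: for every voxel, min squared physical distance to
# any foreground voxel centre.
bf_edt_sq <- function(mask, spacing) {
  d <- dim(mask)
  fg <- which(mask > 0, arr.ind = TRUE)
  out <- array(Inf, d)
  if (nrow(fg) == 0) return(out)
  fg_mm <- sweep(fg, 2, spacing, `*`)
  for (k in seq_len(d[1])) for (j in seq_len(d[2])) for (i in seq_len(d[3])) {
    p <- c(k, j, i) * spacing
    out[k, j, i] <- min(colSums((t(fg_mm) - p)^2))
  }
  out
}

# A tiny straight-tube phantom spec that generates quickly in unit tests.
tiny_tube_spec <- function(seed = 1, ...) {
  phantom_spec(shape = c(48, 40, 40),
               centerline_ctrl_points = cbind(z = c(10, 19, 28, 38),
                                              y = c(20, 21, 20, 19),
                                              x = c(20, 20, 21, 20)),
               radius_profile = 6, aneurysm = NULL, distractors = 0,
               noise_sd = 10, seed = seed, ...)
}
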