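#' Dice similarity coefficient
#'
#' `2|GT intersect P| / (|GT| + |P|)` between two shape-matched binary
#' volumes. Two empty masks are defined to have Dice 1; one empty mask
#' against a non-empty one gives 0.
#'
#' @param gt,pred label [volume()]s (or plain binary arrays) of equal shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(gt, pred) {
  m <- as_mask_pair(gt, pred)
  s <- sum(m$a) + sum(m$b)
  if (s == 0) return(1)
  2 * sum(m$a & m$b) / s
}

#' Jaccard index
#'
#' `|GT intersect P| / |GT union P|`; both masks empty gives 1 by the same
#' convention as [dice()]. Related to Dice by `DSC = 2 JAC / (1 + JAC)`.
#'
#' @inheritParams dice
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(gt, pred) {
  m <- as_mask_pair(gt, pred)
  u <- sum(m$a | m$b)
  if (u == 0) return(1)
  sum(m$a & m$b) / u
}

as_mask_pair <- function(gt, pred) {
  a <- if (is_volume(gt)) gt$data else gt
  b <- if (is_volume(pred)) pred$data else pred
  if (!identical(dim(a), dim(b)))
    stop("masks are not shape-matched: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), call. = FALSE)
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("masks must be binary", call. = FALSE)
  list(a = a > 0, b = b > 0)
}

#' Symmetric surface-to-surface distances
#'
#' Boundary voxels of each mask are the foreground voxels with at least one
#' face-adjacent (6-connected) background neighbour; voxels on the volume
#' border count as boundary. Each boundary's exact Euclidean distance map is
#' computed in physical millimetres, and the symmetric distance set pools the
#' distances from ground-truth boundary voxels to the predicted surface with
#' those from predicted boundary voxels to the ground-truth surface.
#'
#' @inheritParams dice
#' @param spacing voxel spacing `(sz, sy, sx)` in mm; defaults to the
#'   spacing carried by `gt` when it is a [volume()].
#' @return `list(mean =, sd =, max =)` of the symmetric distance set, in mm.
#'   `sd` is the sample standard deviation (0 for a single distance).
#' @export
surface_distances <- function(gt, pred, spacing = NULL) {
  if (is.null(spacing)) {
    spacing <- if (is_volume(gt)) gt$spacing else c(1, 1, 1)
  }
  m <- as_mask_pair(gt, pred)
  if (!any(m$a) || !any(m$b))
    stop("surface distances are undefined for an empty mask", call. = FALSE)
  sa <- boundary_mask(m$a)
  sb <- boundary_mask(m$b)
  da <- sqrt(cpp_edt_sq(sa * 1, as.numeric(spacing)))   # distance to gt surface
  db <- sqrt(cpp_edt_sq(sb * 1, as.numeric(spacing)))   # distance to pred surface
  d <- c(db[sa], da[sb])
  list(mean = mean(d),
       sd = if (length(d) > 1) stats::sd(d) else 0,
       max = max(d))
}

# Foreground voxels with a 6-connected background neighbour (volume border
# counts as background).
boundary_mask <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, by) {
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by == 1L) {
      idx_dst[[ax]] <- seq_len(d[ax] - 1L); idx_src[[ax]] <- 2:d[ax]
    } else {
      idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- seq_len(d[ax] - 1L)
    }
    nb <- array(FALSE, d)
    nb[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    acc & nb
  }
  for (ax in 1:3) for (by in c(1L, -1L)) interior <- shift_and(interior, ax, by)
  mask & !interior
}

#' Evaluate one predicted segmentation against its ground truth
#'
#' Bundles [dice()], [jaccard()] and [surface_distances()] into a one-row
#' report. Dice and Jaccard always satisfy `DSC = 2 JAC / (1 + JAC)`.
#'
#' @inheritParams dice
#' @param case_id identifier copied into the report row.
#' @return A one-row `data.frame` with columns `case_id`, `dsc`, `jac`,
#'   `mean_sd_mm`, `std_sd_mm`, `max_sd_mm`.
#' @export
evaluate_case <- function(gt, pred, case_id = "case") {
  if (is_volume(gt) && is_volume(pred)) {
    check_same_shape(gt, pred)
    if (max(abs(gt$spacing - pred$spacing)) > 1e-6)
      stop("gt and pred spacing differ", call. = FALSE)
  }
  sd3 <- surface_distances(gt, pred)
  data.frame(case_id = case_id,
             dsc = dice(gt, pred),
             jac = jaccard(gt, pred),
             mean_sd_mm = sd3$mean,
             std_sd_mm = sd3$sd,
             max_sd_mm = sd3$max,
             stringsAsFactors = FALSE)
}
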