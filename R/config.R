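#' Default pipeline configuration
#'
#' One nested list holding every tunable of the pipeline, with defaults
#' reproducing the reference full-scale settings: 200/800 HU window, target
#' spacing 0.62 x 0.73 x 0.73 mm, in-plane down-sampling factors 4 (coarse)
#' and 2 (working), cuboid ROI 480 x 144 x 144 voxels (z, y, x), the
#' stage-specific augmentation ranges, Adam with learning rate 1e-4,
#' mini-batches of 20 (coarse) / 10 (single-view) slices, early-stopping
#' patience 15, a 0.05-step threshold grid and stack-smoothing sigma 1.
#'
#' @return A nested configuration list.
#' @seealso [desk_config()] for the phantom-scale variant, [load_config()]
#'   to read and validate a YAML override file.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    preprocess = list(
      window_level = 200, window_width = 800,
      target_spacing = c(0.62, 0.73, 0.73),
      coarse_factor = 4L, working_factor = 2L),
    roi = list(size = c(480L, 144L, 144L)),
    model = list(depth = 2L, base_filters = 8L),
    train = list(
      coarse = list(learning_rate = 1e-4, batch_size = 20L, patience = 15L,
                    max_epochs = 100L, steps_per_epoch = NULL),
      view   = list(learning_rate = 1e-4, batch_size = 10L, patience = 15L,
                    max_epochs = 100L, steps_per_epoch = NULL)),
    augment = list(
      coarse  = list(rotation_deg = c(-10, 10), shift_x_px = c(-20, 20),
                     shift_y_px = c(-22, 22), zoom = c(0.85, 1.15)),
      axial   = list(rotation_deg = c(-7, 7), shift_x_px = c(-22, 22),
                     shift_y_px = c(-22, 22), zoom = c(0.85, 1.15)),
      sagittal = list(rotation_deg = c(-7, 7), shift_x_px = c(-22, 22),
                      shift_y_px = c(-72, 72), zoom = c(0.85, 1.15)),
      coronal = list(rotation_deg = c(-7, 7), shift_x_px = c(-22, 22),
                     shift_y_px = c(-72, 72), zoom = c(0.85, 1.15))),
    threshold_grid = seq(0.05, 0.95, by = 0.05),
    sigma = 1.0,
    fusion = "combined")
}

#' Phantom-scale configuration
#'
#' The [default_config()] adapted to the package's 128 x 96 x 96 synthetic
#' phantoms at 1 mm spacing: the input grid is kept (no resampling), the
#' cuboid ROI shrinks to 128 x 48 x 48 working-grid voxels, models stay at
#' depth 2 with 8 base filters, training runs 10 epochs of 40 Adam steps at
#' learning rate 1e-3, and augmentation shifts are scaled down in proportion
#' to the smaller slice sizes (rotation and zoom ranges unchanged).
#'
#' @param seed master seed for the whole experiment.
#' @return A nested configuration list.
#' @export
desk_config <- function(seed = 1L) {
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  cfg$preprocess$target_spacing <- NULL
  cfg$roi$size <- c(128L, 48L, 48L)
  cfg$train$coarse[c("learning_rate", "max_epochs", "steps_per_epoch")] <-
    list(1e-3, 10L, 40L)
  cfg$train$view[c("learning_rate", "max_epochs", "steps_per_epoch")] <-
    list(1e-3, 10L, 40L)
  # shift ranges scaled by desk/full slice-size ratios (24/128, 48/144, 128/480)
  cfg$augment$coarse[c("shift_x_px", "shift_y_px")] <- list(c(-4, 4), c(-4, 4))
  cfg$augment$axial[c("shift_x_px", "shift_y_px")] <- list(c(-7, 7), c(-7, 7))
  cfg$augment$sagittal[c("shift_x_px", "shift_y_px")] <- list(c(-7, 7), c(-19, 19))
  cfg$augment$coronal[c("shift_x_px", "shift_y_px")] <- list(c(-7, 7), c(-19, 19))
  cfg
}

#' Load and validate a YAML configuration
#'
#' Reads a YAML file and merges it over [default_config()] (or another
#' base). Unknown keys at any nesting level are rejected, so typos fail
#' loudly rather than being silently ignored.
#'
#' @param path YAML file path.
#' @param base configuration list supplying defaults.
#' @return The merged configuration list.
#' @export
load_config <- function(path, base = default_config()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(base)
  merge_config(base, user, "")
}

merge_config <- function(base, user, where) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0)
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(where, unknown, collapse = ", "), call. = FALSE)
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && !is.null(names(base[[nm]])))
      merge_config(base[[nm]], user[[nm]], paste0(where, nm, "/"))
    else user[[nm]]
  }
  base
}

#' Write a configuration to YAML
#' @param cfg a configuration list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
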