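# Training-time slice augmentation: random horizontal flip, small-angle
# rotation (zero-filled corners, matching the dark background), and slight
# multiplicative intensity scaling, in that order, with a final clamp to
# [0, 1]. Applied to training partitions only; validation and test images
# pass through untouched.

#' Augmentation configuration
#'
#' @param horizontal_flip_prob probability of a left-right flip (default 0.5).
#' @param rotation_limit_degrees max absolute rotation angle; the angle is
#'   drawn uniformly in `[-limit, +limit]` (default 10).
#' @param intensity_scale_range multiplicative intensity interval around 1
#'   (default `c(0.9, 1.1)`).
#' @param enabled master switch; when `FALSE`, [augment_slice()] is the
#'   identity.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(horizontal_flip_prob = 0.5,
                                rotation_limit_degrees = 10,
                                intensity_scale_range = c(0.9, 1.1),
                                enabled = TRUE) {
  if (horizontal_flip_prob < 0 || horizontal_flip_prob > 1)
    nn_stop("config_error", "horizontal_flip_prob must lie in [0, 1]")
  if (rotation_limit_degrees < 0)
    nn_stop("config_error", "rotation_limit_degrees must be >= 0")
  if (length(intensity_scale_range) != 2 || any(intensity_scale_range <= 0) ||
      diff(intensity_scale_range) < 0)
    nn_stop("config_error", "intensity_scale_range must be a positive interval")
  structure(list(horizontal_flip_prob = horizontal_flip_prob,
                 rotation_limit_degrees = rotation_limit_degrees,
                 intensity_scale_range = intensity_scale_range,
                 enabled = enabled),
            class = "augmentation_config")
}

#' Augment one slice
#'
#' Uses the current RNG state. With `enabled = FALSE` the input is returned
#' unchanged. `force` overrides the random draws for testing (list with any
#' of `flip` (logical), `angle` (degrees), `scale`).
#'
#' @param image matrix with values in `[0, 1]`.
#' @param config an [augmentation_config()].
#' @param force optional list of forced draws.
#' @return augmented matrix, clamped to `[0, 1]`.
#' @export
augment_slice <- function(image, config = augmentation_config(), force = NULL) {
  if (!config$enabled && is.null(force)) return(image)
  flip <- if (!is.null(force$flip)) force$flip else
    runif(1) < config$horizontal_flip_prob
  angle <- if (!is.null(force$angle)) force$angle else
    runif(1, -config$rotation_limit_degrees, config$rotation_limit_degrees)
  scl <- if (!is.null(force$scale)) force$scale else
    runif(1, config$intensity_scale_range[1], config$intensity_scale_range[2])
  out <- image
  if (abs(angle) > 1e-12) out <- rotate_zero_fill(out, angle)
  if (isTRUE(flip)) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  out <- out * scl
  pmin(pmax(out, 0), 1)
}

# Rotation about the image center with bilinear interpolation and zero fill.
rotate_zero_fill <- function(m, angle_deg) {
  r <- EBImage::rotate(m, angle_deg, filter = "bilinear",
                       output.dim = dim(m), bg.col = 0)
  matrix(as.numeric(r), nrow(m), ncol(m))
}
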