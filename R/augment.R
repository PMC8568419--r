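#' Construct affine augmentation parameters
#'
#' One CT-aware augmentation is a joint affine transform applied identically
#' to a slice and its mask: a bounded translation (at most 5% of the image
#' side per axis), an optional horizontal flip, and a rotation of at most 20
#' degrees about the image centre, emulating patient positioning variation.
#'
#' @param dx,dy Signed shift as a fraction of the image side (column/row
#'   direction), each in `[-0.05, 0.05]`.
#' @param hflip Logical, horizontal (left-right) flip.
#' @param angle_deg Rotation angle in degrees, in `[-20, 20]`.
#' @param max_shift,max_angle Bounds used for validation.
#' @return An `augment_params` object.
#' @export
augment_params <- function(dx = 0, dy = 0, hflip = FALSE, angle_deg = 0,
                           max_shift = 0.05, max_angle = 20) {
  if (abs(dx) > max_shift + 1e-12 || abs(dy) > max_shift + 1e-12)
    stopf("shift fraction exceeds %g: dx=%g dy=%g", max_shift, dx, dy)
  if (abs(angle_deg) > max_angle + 1e-9)
    stopf("rotation angle exceeds %g degrees: %g", max_angle, angle_deg)
  structure(list(dx = dx, dy = dy, hflip = isTRUE(hflip), angle_deg = angle_deg),
            class = "augment_params")
}

#' Sample augmentation parameters
#'
#' Draws `dx, dy ~ U(-max_shift, max_shift)`, `hflip ~ Bernoulli(1/2)` and
#' `angle ~ U(-max_angle, max_angle)` from the current RNG stream (seed the
#' stream, or use the `seed` argument, for reproducibility).
#'
#' @inheritParams augment_params
#' @param seed Optional integer seed.
#' @return An `augment_params` object.
#' @export
sample_augment_params <- function(max_shift = 0.05, max_angle = 20, seed = NULL) {
  local_seed(seed, {
    u <- runif(4)
    augment_params(dx = (2 * u[1] - 1) * max_shift,
                   dy = (2 * u[2] - 1) * max_shift,
                   hflip = u[3] < 0.5,
                   angle_deg = (2 * u[4] - 1) * max_angle,
                   max_shift = max_shift, max_angle = max_angle)
  })
}

# Inverse-map matrix/offset for cpp_warp: forward transform is
# flip, then rotation, then shift (fixed composition order), so the source
# point for a destination pixel is F^-1 R^-1 (dest - shift).
warp_matrices <- function(params, H, W) {
  th <- params$angle_deg * pi / 180
  Rinv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)  # R(-th) in (row, col)
  Finv <- diag(c(1, if (params$hflip) -1 else 1))
  A <- Finv %*% Rinv
  shift <- c(params$dy * H, params$dx * W)
  list(A = A, t = as.numeric(-A %*% shift))
}

#' Apply one augmentation jointly to a slice and its mask
#'
#' The image is resampled bilinearly (out-of-frame filled with air, -1000 HU,
#' then re-quantised to integer HU); the mask with nearest-neighbour (filled
#' with 0), so it stays strictly binary. Identity parameters return both
#' inputs bit-identically.
#'
#' @param image HU matrix.
#' @param mask Binary 0/1 matrix of the same shape.
#' @param params An [augment_params()].
#' @return List with transformed `image` and `mask`.
#' @examples
#' ph <- generate_phantom(phantom_spec(image_size = 64), seed = 1)
#' out <- apply_augment(ph$image, ph$mask, augment_params(dx = 0.05))
#' @export
apply_augment <- function(image, mask, params) {
  if (!inherits(params, "augment_params")) stopf("params must be augment_params")
  check_same_shape(image, mask)
  if (!is_binary_mask(mask)) stopf("mask must be a binary 0/1 matrix")
  wm <- warp_matrices(params, nrow(image), ncol(image))
  img <- cpp_warp(image, wm$A, wm$t, bilinear = TRUE, fill = -1000)
  img <- matrix(as.integer(round(img)), nrow(image), ncol(image))
  msk <- cpp_warp(mask, wm$A, wm$t, bilinear = FALSE, fill = 0)
  msk <- matrix(as.integer(msk), nrow(mask), ncol(mask))
  list(image = img, mask = msk)
}

#' Expand a training set by CT-aware augmentation
#'
#' Returns each original pair once plus `factor - 1` independently augmented
#' copies, materialised up front (a fixed augmented set, not per-epoch
#' resampling). Each copy records its source index and the sampled parameters
#' so it can be reproduced exactly.
#'
#' @param pairs List of `list(image, mask, ...)` training pairs.
#' @param factor Total expansion factor (>= 1); 616 inputs with the default 5
#'   give 3080 outputs.
#' @param seed Integer seed driving all parameter draws.
#' @inheritParams augment_params
#' @return A list of `factor * length(pairs)` pairs; augmented copies carry
#'   `source_index` and `params` fields.
#' @export
augment_dataset <- function(pairs, factor = 5L, seed = 1L,
                            max_shift = 0.05, max_angle = 20) {
  if (factor < 1) stopf("augmentation factor must be >= 1 (got %g)", factor)
  factor <- as.integer(factor)
  local_seed(seed, {
    out <- vector("list", factor * length(pairs))
    k <- 0L
    for (i in seq_along(pairs)) {
      k <- k + 1L
      out[[k]] <- pairs[[i]]
      if (factor > 1L) {
        for (j in seq_len(factor - 1L)) {
          p <- sample_augment_params(max_shift, max_angle)
          aug <- apply_augment(pairs[[i]]$image, pairs[[i]]$mask, p)
          rec <- pairs[[i]]
          rec$image <- aug$image
          rec$mask <- aug$mask
          rec$source_index <- i
          rec$params <- p
          k <- k + 1L
          out[[k]] <- rec
        }
      }
    }
    out
  })
}

#' @export
print.augment_params <- function(x, ...) {
  cat(sprintf("augment_params: dx=%+.4f dy=%+.4f hflip=%s angle=%+.2f deg\n",
              x$dx, x$dy, x$hflip, x$angle_deg))
  invisible(x)
}
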