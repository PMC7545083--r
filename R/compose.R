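#' Signal placement locations
#'
#' The eight possible signal positions within the stimulus grid: four on
#' each side of the vertical midline (left/right), at four elevations
#' (top, mid/top, mid/bottom, bottom). Location ids 0-3 are the left-side
#' elevations top to bottom; 4-7 the right side. Signals on the left of
#' the midline are presented in the left visual field and vice versa.
#'
#' @param signal_width,signal_height Dimensions of the signal image (px).
#' @inheritParams angular_size
#' @return A tibble with one row per location: `location_id` (0-7),
#'   `side` ("left"/"right"), `elevation`, `visual_field` ("LVF"/"RVF"),
#'   and the 1-based top-left `row0`, `col0` of the signal footprint.
#' @examples
#' signal_locations(110, 150)
#' @export
signal_locations <- function(signal_width, signal_height,
                             geometry = geometry_config()) {
  n <- geometry$image_px
  half <- n %/% 2
  if (signal_width > half || signal_height > n) {
    abort("Signal image does not fit within one side of the grid.")
  }
  elevations <- c("top", "mid_top", "mid_bottom", "bottom")
  rows0 <- 1L + as.integer(round((seq_len(4) - 1) * (n - signal_height) / 3))
  col_left <- 1L + (half - as.integer(signal_width)) %/% 2L
  col_right <- half + col_left
  tibble::tibble(
    location_id = 0:7,
    side = rep(c("left", "right"), each = 4L),
    elevation = rep(elevations, 2L),
    visual_field = rep(c("LVF", "RVF"), each = 4L),
    row0 = rep(rows0, 2L),
    col0 = rep(c(col_left, col_right), each = 4L)
  )
}

#' Place a signal image within a noise field
#'
#' Overwrites the signal footprint at one of the eight lateralised
#' locations with the signal pixels; all other field pixels are untouched.
#'
#' @param signal Numeric matrix (prepared signal image).
#' @param field Numeric matrix, the background noise field (square,
#'   `image_px` on a side).
#' @param location_id Integer 0-7, see [signal_locations()].
#' @inheritParams angular_size
#' @return The field matrix with the signal embedded.
#' @export
place_signal <- function(signal, field, location_id,
                         geometry = geometry_config()) {
  stop_if_not_matrix(signal, "signal")
  stop_if_not_matrix(field, "field")
  if (!is_scalar_number(location_id) || location_id %% 1 != 0 ||
      location_id < 0 || location_id > 7) {
    abort("`location_id` must be an integer in 0..7.")
  }
  loc <- signal_locations(ncol(signal), nrow(signal), geometry)
  loc <- loc[loc$location_id == location_id, ]
  rows <- loc$row0:(loc$row0 + nrow(signal) - 1L)
  cols <- loc$col0:(loc$col0 + ncol(signal) - 1L)
  if (max(rows) > nrow(field) || max(cols) > ncol(field)) {
    abort("Signal does not fit inside the field at this location.")
  }
  field[rows, cols] <- signal
  field
}

#' Pixel-wise signal/noise mixing
#'
#' Combines a signal-in-noise image with its noise-only companion by
#' designating an exact count of pixel positions as noise: exactly
#' `round(noise_fraction * N)` positions, drawn uniformly at random
#' without replacement, take their value from `noise_only`; the remainder
#' keep the `signal_in_noise` value. This degrades the spatial correlation
#' that carries the signal rather than the per-pixel signal-to-noise
#' amplitude ratio.
#'
#' @param signal_in_noise,noise_only Numeric matrices of identical shape.
#' @param noise_fraction Proportion of pixels designated noise, in
#'   \eqn{[0, 1]}.
#' @param seed Optional seed; the designation is deterministic per seed.
#' @return The mixed matrix, with attribute `n_noise_pixels` recording the
#'   exact number of noise-designated positions.
#' @examples
#' a <- matrix(0, 20, 20); b <- matrix(1, 20, 20)
#' attr(pixel_mix(a, b, 0.44, seed = 1), "n_noise_pixels") # 176
#' @export
pixel_mix <- function(signal_in_noise, noise_only, noise_fraction,
                      seed = NULL) {
  stop_if_not_matrix(signal_in_noise, "signal_in_noise")
  stop_if_not_matrix(noise_only, "noise_only")
  if (!identical(dim(signal_in_noise), dim(noise_only))) {
    abort("`signal_in_noise` and `noise_only` must have identical shape.")
  }
  if (!is_scalar_number(noise_fraction) ||
      noise_fraction < 0 || noise_fraction > 1) {
    abort("`noise_fraction` must lie in [0, 1].")
  }
  n <- length(signal_in_noise)
  k <- as.integer(round(noise_fraction * n))
  out <- signal_in_noise
  if (k > 0L) {
    idx <- with_seed_if(seed, sample.int(n, k))
    out[idx] <- noise_only[idx]
  }
  attr(out, "n_noise_pixels") <- k
  out
}

#' RMS contrast of an image
#'
#' The conventional contrast measure for non-periodic stimuli: the
#' population standard deviation of pixel luminance divided by the mean
#' luminance. Invariant under multiplicative rescaling of the image.
#'
#' @param image Non-empty numeric matrix with positive mean.
#' @return A single non-negative number.
#' @examples
#' compute_rms_contrast(matrix(c(96, 160), 10, 10)) # 0.25
#' @export
compute_rms_contrast <- function(image) {
  stop_if_not_matrix(image, "image")
  m <- mean(image)
  if (m <= 0) abort("`image` must have positive mean luminance.")
  sqrt(mean((image - m)^2)) / m
}

#' Rescale an image to a target RMS contrast
#'
#' Scales deviations about the mean so that [compute_rms_contrast()] of
#' the output equals `target_rms`; the mean luminance is preserved
#' exactly.
#'
#' @param image Non-constant numeric matrix with positive mean.
#' @param target_rms Target RMS contrast (non-negative).
#' @return Rescaled matrix.
#' @export
scale_to_rms <- function(image, target_rms) {
  stop_if_not_matrix(image, "image")
  if (!is_scalar_number(target_rms) || target_rms < 0) {
    abort("`target_rms` must be a non-negative number.")
  }
  m <- mean(image)
  if (m <= 0) abort("`image` must have positive mean luminance.")
  s <- sqrt(mean((image - m)^2))
  if (s == 0) abort("Cannot rescale a constant image to a nonzero contrast.")
  (image - m) * (target_rms * m / s) + m
}

#' Quantise an image to the 8-bit display range
#'
#' Rounds to integer grey levels and clips to \eqn{[0, 255]}. The clipped
#' fraction (pixels outside the range before clipping) is recorded as an
#' attribute so generation code can enforce its clipping tolerance.
#'
#' @param image Numeric matrix.
#' @return Integer-valued matrix in \eqn{[0, 255]} with attribute
#'   `clipped_fraction`.
#' @export
quantize_8bit <- function(image) {
  stop_if_not_matrix(image, "image")
  r <- round(image)
  clipped <- mean(r < 0 | r > 255)
  out <- pmin(pmax(r, 0), 255)
  attr(out, "clipped_fraction") <- clipped
  out
}
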