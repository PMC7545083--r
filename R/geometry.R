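#' Stimulus geometry configuration
#'
#' Collects the spatial and temporal constants of the display geometry:
#' the side length of the square stimulus grid in pixels and in degrees of
#' visual angle, the standardised signal-image height, the lateral offset of
#' the stimulus from fixation, the viewing distance and the presentation
#' duration. All spatial-frequency arithmetic in the package uses the
#' stimulus-intrinsic scale `image_px / image_deg` (pixels per degree).
#'
#' @param image_px Integer side length of the full stimulus grid (pixels).
#' @param image_deg Angular side length of the full stimulus (degrees of
#'   visual angle).
#' @param signal_height_px Height the signal images are standardised to
#'   (pixels); must be smaller than `image_px`.
#' @param eccentricity_deg Offset from the fixation point to the inner edge
#'   of the stimulus (degrees).
#' @param viewing_distance_mm Viewing distance (millimetres).
#' @param duration_ms Stimulus presentation duration (milliseconds),
#'   rectangular temporal envelope.
#'
#' @return A list of class `geometry_config`.
#' @examples
#' geom <- geometry_config()
#' pixels_per_degree(geom)
#' @export
geometry_config <- function(image_px = 400L,
                            image_deg = 4.2,
                            signal_height_px = 150L,
                            eccentricity_deg = 1.96,
                            viewing_distance_mm = 570,
                            duration_ms = 180) {
  image_px <- as.integer(image_px)
  signal_height_px <- as.integer(signal_height_px)
  if (!is_scalar_number(image_deg) || image_deg <= 0) {
    abort("`image_deg` must be a positive number.")
  }
  if (is.na(image_px) || is.na(signal_height_px) ||
      image_px <= signal_height_px || signal_height_px <= 0) {
    abort("Require `image_px` > `signal_height_px` > 0.")
  }
  structure(
    list(
      image_px = image_px,
      image_deg = image_deg,
      signal_height_px = signal_height_px,
      eccentricity_deg = eccentricity_deg,
      viewing_distance_mm = viewing_distance_mm,
      duration_ms = duration_ms
    ),
    class = "geometry_config"
  )
}

#' @rdname geometry_config
#' @param geometry A `geometry_config`.
#' @export
pixels_per_degree <- function(geometry = geometry_config()) {
  geometry$image_px / geometry$image_deg
}

#' Angular size of a pixel extent
#'
#' Converts a pixel extent to degrees of visual angle on the
#' stimulus-intrinsic scale (`image_deg / image_px` degrees per pixel), the
#' scale on which the full grid subtends exactly `image_deg`.
#'
#' @param pixels Non-negative pixel extent (vectorised).
#' @inheritParams pixels_per_degree
#' @return Degrees of visual angle.
#' @examples
#' angular_size(400) # 4.2
#' angular_size(150) # ~1.57
#' @export
angular_size <- function(pixels, geometry = geometry_config()) {
  if (any(pixels < 0)) abort("`pixels` must be non-negative.")
  pixels * geometry$image_deg / geometry$image_px
}

#' Spatial-frequency band-pass filter specification
#'
#' An isotropic Gaussian band-pass filter on log spatial frequency, defined
#' by its centre frequency in cycles per degree and its full bandwidth in
#' octaves at half height: the gain is 1 at `center_cpd` and 0.5 at
#' `center_cpd * 2^(-bandwidth/2)` and `center_cpd * 2^(+bandwidth/2)`
#' (a frequency ratio of exactly `2^bandwidth` between the half-height
#' points).
#'
#' @param center_cpd Centre spatial frequency (cycles/degree).
#' @param bandwidth_octaves Full bandwidth at half height (octaves).
#' @return A list of class `filter_spec`.
#' @examples
#' spec <- filter_spec()
#' bandpass_gain(c(1.5, 1.5 / sqrt(2), 1.5 * sqrt(2)), spec)
#' @export
filter_spec <- function(center_cpd = 1.5, bandwidth_octaves = 1) {
  if (!is_scalar_number(center_cpd) || center_cpd <= 0) {
    abort("`center_cpd` must be a positive number.")
  }
  if (!is_scalar_number(bandwidth_octaves) || bandwidth_octaves <= 0) {
    abort("`bandwidth_octaves` must be a positive number.")
  }
  structure(
    list(center_cpd = center_cpd, bandwidth_octaves = bandwidth_octaves),
    class = "filter_spec"
  )
}
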