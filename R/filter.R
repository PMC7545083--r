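#' Gain of the octave-band Gaussian filter
#'
#' The filter is Gaussian on log spatial frequency with unit gain at the
#' centre frequency and gain 0.5 at the half-height frequencies
#' `center_cpd * 2^(+-bandwidth/2)`; with a one-octave bandwidth the two
#' half-height frequencies are a factor of exactly 2 apart. A Gaussian on
#' log frequency is the only isotropic Gaussian profile that meets both
#' half-height constraints simultaneously.
#'
#' @param f_cpd Spatial frequency (cycles/degree); vectorised,
#'   non-negative. Gain at zero frequency is 0 (DC is handled by
#'   recentring in [bandpass_filter()]).
#' @param spec A [filter_spec()].
#' @return Gain values in \eqn{[0, 1]}.
#' @examples
#' bandpass_gain(c(1.5, 1.5 * 2^-0.5, 1.5 * 2^0.5), filter_spec())
#' @export
bandpass_gain <- function(f_cpd, spec = filter_spec()) {
  g <- numeric(length(f_cpd))
  pos <- f_cpd > 0
  half_bw <- spec$bandwidth_octaves / 2
  g[pos] <- exp(-log(2) * (log2(f_cpd[pos] / spec$center_cpd) / half_bw)^2)
  g
}

#' Band-pass filter an image in the frequency domain
#'
#' Applies the isotropic octave-band Gaussian gain of [bandpass_gain()] to
#' the image's spatial-frequency content. Frequencies are interpreted on
#' the stimulus-intrinsic scale (`image_px / image_deg` pixels per
#' degree). The output is recentred on the original mean luminance, so a
#' pure DC image passes through unchanged; optionally the result is also
#' rescaled to a target RMS contrast.
#'
#' @param image Square numeric matrix.
#' @param spec A [filter_spec()].
#' @inheritParams angular_size
#' @param rescale_rms Optional target RMS contrast applied after
#'   filtering (`NULL` leaves the filtered contrast as is).
#' @return Filtered matrix with the same dimensions and mean.
#' @export
bandpass_filter <- function(image, spec = filter_spec(),
                            geometry = geometry_config(),
                            rescale_rms = NULL) {
  stop_if_not_matrix(image, "image")
  if (nrow(image) != ncol(image)) abort("`image` must be square.")
  n <- nrow(image)
  deg_per_image <- n / pixels_per_degree(geometry)
  nyquist_cpd <- (n / 2) / deg_per_image
  if (spec$center_cpd >= nyquist_cpd) {
    abort(sprintf(
      "Centre frequency %.3g cpd is at or above Nyquist (%.3g cpd) for this geometry.",
      spec$center_cpd, nyquist_cpd
    ))
  }
  m <- mean(image)
  f_cpd <- radial_frequency(n, n) / deg_per_image
  gain <- matrix(bandpass_gain(as.numeric(f_cpd), spec), n, n)
  out <- Re(fft(fft(image - m) * gain, inverse = TRUE)) / (n * n) + m
  if (!is.null(rescale_rms)) out <- scale_to_rms(out, rescale_rms)
  out
}
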