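# Signed integer wavenumbers for an FFT axis of length n (cycles per image).
fft_wavenumbers <- function(n) {
  half <- n %/% 2
  c(0:half, if (n - half - 1L > 0) -((n - half - 1L):1))
}

# Radial spatial frequency (cycles per image) on the FFT grid of an
# nrow x ncol image. Symmetric under frequency negation, so real-input
# conjugate symmetry is preserved by any radial gain. Cached per grid
# size: the same few grids are reused hundreds of times per stimulus set.
.freq_cache <- new.env(parent = emptyenv())

radial_frequency <- function(nrow, ncol) {
  key <- paste0(nrow, "x", ncol)
  got <- .freq_cache[[key]]
  if (!is.null(got)) return(got)
  ky <- fft_wavenumbers(nrow)
  kx <- fft_wavenumbers(ncol)
  f <- sqrt(outer(ky^2, kx^2, "+"))
  .freq_cache[[key]] <- f
  f
}

#' Generate a pink (1/f) noise field
#'
#' Synthesises a two-dimensional luminance noise field whose amplitude
#' spectrum falls as 1/f with radial spatial frequency, mimicking the
#' second-order statistics of natural scenes. Construction is in the
#' frequency domain: a deterministic 1/f amplitude envelope is combined
#' with uniform random phase (obtained by normalising the spectrum of a
#' white Gaussian field, which guarantees conjugate symmetry), the DC term
#' is zeroed, and the inverse transform is recentred on `mean_level` and
#' scaled to the requested RMS contrast.
#'
#' @param width,height Field dimensions in pixels (at least 8).
#' @param mean_level Mean luminance of the field (8-bit display units).
#' @param target_rms RMS contrast (population SD / mean) of the returned
#'   field.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   field exactly, without disturbing the caller's RNG stream.
#'
#' @return A `height` x `width` numeric matrix with mean exactly
#'   `mean_level` and RMS contrast exactly `target_rms` (before any
#'   quantisation).
#' @examples
#' nf <- generate_pink_noise(64, 64, seed = 1)
#' compute_rms_contrast(nf)
#' @export
generate_pink_noise <- function(width, height, mean_level = 128,
                                target_rms = 0.30, seed = NULL) {
  if (!is_scalar_number(width) || !is_scalar_number(height) ||
      width < 8 || height < 8) {
    abort("`width` and `height` must be at least 8.")
  }
  if (!is_scalar_number(mean_level) || mean_level <= 0) {
    abort("`mean_level` must be positive.")
  }
  width <- as.integer(width)
  height <- as.integer(height)
  w <- with_seed_if(seed, matrix(rnorm(width * height), height, width))
  W <- fft(w)
  f <- radial_frequency(height, width)
  envelope <- ifelse(f > 0, 1 / f, 0)
  S <- (W / pmax(Mod(W), .Machine$double.xmin)) * envelope
  x <- Re(fft(S, inverse = TRUE)) / (width * height)
  # DC was zeroed so mean(x) == 0 up to rounding; normalise exactly.
  x <- x - mean(x)
  x <- x / sqrt(mean(x^2)) * (target_rms * mean_level) + mean_level
  x
}

#' Fitted log-log slope of the radially averaged amplitude spectrum
#'
#' Measures how image amplitude falls with spatial frequency: amplitudes at
#' each FFT cell are binned by rounded radial frequency (cycles per image),
#' averaged within bins, and a least-squares line is fitted to log mean
#' amplitude against log frequency, excluding the DC term. A 1/f field has
#' a slope near -1.
#'
#' @param image Numeric matrix.
#' @param max_frequency Highest radial bin used in the fit; defaults to the
#'   Nyquist frequency of the shorter image side.
#' @return The fitted slope (a single number).
#' @examples
#' spectral_slope(generate_pink_noise(64, 64, seed = 1))
#' @export
spectral_slope <- function(image, max_frequency = NULL) {
  stop_if_not_matrix(image, "image")
  amp <- Mod(fft(image - mean(image)))
  f <- radial_frequency(nrow(image), ncol(image))
  if (is.null(max_frequency)) max_frequency <- min(dim(image)) %/% 2
  fb <- round(f)
  keep <- fb >= 1 & fb <= max_frequency
  m <- tapply(amp[keep], fb[keep], mean)
  fr <- as.numeric(names(m))
  ok <- m > 0
  unname(coef(lm(log(m[ok]) ~ log(fr[ok])))[2])
}
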