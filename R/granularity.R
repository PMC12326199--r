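#' Geometric series of spatial scales
#'
#' Pattern energy is measured over a log-spaced ladder of spatial scales:
#' starting at `min_scale` pixels, each successive scale multiplies by
#' `multiplier`, truncated at the last value not exceeding `max_scale`. The
#' study convention is a 1.414 multiplier from 2 px up to 724 px (the extent
#' of the smallest analysed flank); callers analysing other data should cap
#' the series at their smallest ROI extent.
#'
#' @param min_scale First scale in pixels (>= 2, the Nyquist-safe floor).
#' @param multiplier Ratio between successive scales (> 1).
#' @param max_scale Largest admissible scale in pixels.
#' @return A numeric vector of scales (class `scale_series`).
#' @export
#' @examples
#' length(build_scale_series()) # 18
build_scale_series <- function(min_scale = 2, multiplier = 1.414,
                               max_scale = 724) {
  stopifnot_scalar_positive(min_scale, "min_scale")
  stopifnot_scalar_positive(max_scale, "max_scale")
  if (min_scale < 2) {
    abort_chromatch("`min_scale` must be at least 2 pixels.", "chromatch_domain_error")
  }
  if (!is_scalar_number(multiplier) || multiplier <= 1) {
    abort_chromatch("`multiplier` must exceed 1.", "chromatch_domain_error")
  }
  if (max_scale < min_scale) {
    abort_chromatch("`max_scale` below `min_scale`: empty scale series.",
                    "chromatch_empty_series_error")
  }
  k_max <- floor(log(max_scale / min_scale) / log(multiplier) + 1e-9)
  scales <- min_scale * multiplier^(0:k_max)
  structure(scales, multiplier = multiplier, class = c("scale_series", "numeric"))
}

#' @export
print.scale_series <- function(x, ...) {
  cat(sprintf("<scale_series> %d scales, %.4g..%.4g px (x%.4g)\n",
              length(x), x[1], x[length(x)], attr(x, "multiplier")))
  invisible(x)
}

series_multiplier <- function(series) {
  m <- attr(series, "multiplier")
  if (is.null(m)) {
    if (length(series) < 2L) {
      abort_chromatch("Cannot infer the series multiplier from a single scale.",
                      "chromatch_domain_error")
    }
    m <- series[2] / series[1]
  }
  m
}

# Gaussian low-pass transfer function evaluated on the padded image's
# frequency grid. sigma = scale * sqrt(ln 2) / pi places the continuum peak
# of each difference-of-Gaussians band at a sinusoid period equal to the
# band's upper scale (for a sqrt(2) multiplier).
gauss_lowpass <- function(f2, scale_px) {
  sigma <- scale_px * sqrt(log(2)) / pi
  exp(-2 * pi^2 * sigma^2 * f2)
}

freq_sq_grid <- function(n, m) {
  fu <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
  fv <- c(0:floor(m / 2), -(ceiling(m / 2) - 1):-1)[1:m] / m
  outer(fu^2, rep(1, m)) + outer(rep(1, n), fv^2)
}

mirror_pad <- function(mat, pad) {
  n <- nrow(mat); m <- ncol(mat)
  pr <- min(pad, n); pc <- min(pad, m)
  ri <- c(rev(seq_len(pr)), seq_len(n), n + 1 - seq_len(pr))
  ci <- c(rev(seq_len(pc)), seq_len(m), m + 1 - seq_len(pc))
  list(mat = mat[ri, ci, drop = FALSE], pr = pr, pc = pc)
}

as_luminance_matrix <- function(luminance_image) {
  if (inherits(luminance_image, "multiband_image")) {
    if (dim(luminance_image$pixels)[3] != 1L) {
      abort_chromatch("Pattern analysis expects a single-band (luminance) image.",
                      "chromatch_shape_error")
    }
    luminance_image$pixels[, , 1]
  } else if (is.matrix(luminance_image)) {
    luminance_image
  } else {
    abort_chromatch("`luminance_image` must be a matrix or single-band multiband_image.",
                    "chromatch_shape_error")
  }
}

#' Pattern energy in one spatial-scale band
#'
#' Bandpass-filters the luminance image in the frequency domain and returns
#' the "energy" of the band: the standard deviation of the filtered values
#' over the masked pixels. The bandpass is a difference of Gaussian low-pass
#' transfer functions whose widths are proportional to the two bounding
#' scales; the full image is mirror-padded and filtered whole (the mask only
#' restricts the energy computation), so ROI edges do not leak ringing into
#' the measurement.
#'
#' @param luminance_image Numeric matrix (or single-band [multiband_image()]),
#'   typically the double-cone catch image.
#' @param mask A [roi_mask()] matching the image.
#' @param scale_low,scale_high Band bounds in pixels, `scale_low < scale_high`.
#' @return Non-negative scalar energy.
#' @export
bandpass_energy <- function(luminance_image, mask, scale_low, scale_high) {
  lum <- as_luminance_matrix(luminance_image)
  stopifnot(inherits(mask, "roi_mask"))
  if (!identical(dim(mask$pixels), dim(lum))) {
    abort_chromatch("Mask dimensions do not match the image.", "chromatch_shape_error")
  }
  stopifnot_scalar_positive(scale_low, "scale_low")
  stopifnot_scalar_positive(scale_high, "scale_high")
  if (scale_low >= scale_high) {
    abort_chromatch("`scale_low` must be below `scale_high`.", "chromatch_domain_error")
  }
  if (scale_high > min(dim(lum))) {
    abort_chromatch("Scale band exceeds the image extent.",
                    "chromatch_scale_out_of_range_error")
  }
  padded <- mirror_pad(lum, ceiling(scale_high))
  F <- stats::fft(padded$mat)
  f2 <- freq_sq_grid(nrow(padded$mat), ncol(padded$mat))
  H <- gauss_lowpass(f2, scale_low) - gauss_lowpass(f2, scale_high)
  filt <- Re(stats::fft(F * H, inverse = TRUE)) / length(F)
  core <- filt[padded$pr + seq_len(nrow(lum)), padded$pc + seq_len(ncol(lum))]
  sd(core[mask$pixels])
}

#' Pattern-energy spectrum over a scale series
#'
#' One bandpass energy per scale: scale `s_k`'s band spans
#' `(s_k / multiplier, s_k]`. The padded image is Fourier-transformed once
#' and each band is assembled from two Gaussian low-pass responses.
#'
#' @inheritParams bandpass_energy
#' @param series A [build_scale_series()] (its largest scale must fit the
#'   image).
#' @return A tibble with columns `scale_px`, `energy` (class
#'   `energy_spectrum`), carrying the series multiplier as an attribute.
#' @export
energy_spectrum <- function(luminance_image, mask, series = build_scale_series()) {
  lum <- as_luminance_matrix(luminance_image)
  stopifnot(inherits(mask, "roi_mask"))
  if (!identical(dim(mask$pixels), dim(lum))) {
    abort_chromatch("Mask dimensions do not match the image.", "chromatch_shape_error")
  }
  scales <- as.numeric(series)
  if (length(scales) < 1L) {
    abort_chromatch("Empty scale series.", "chromatch_empty_series_error")
  }
  mult <- series_multiplier(series)
  if (max(scales) > min(dim(lum))) {
    abort_chromatch("Largest scale exceeds the image extent; cap the series at the ROI size.",
                    "chromatch_scale_out_of_range_error")
  }
  padded <- mirror_pad(lum, ceiling(max(scales)))
  F <- stats::fft(padded$mat)
  f2 <- freq_sq_grid(nrow(padded$mat), ncol(padded$mat))
  ri <- padded$pr + seq_len(nrow(lum))
  ci <- padded$pc + seq_len(ncol(lum))
  bounds <- c(scales[1] / mult, scales)
  lowpassed <- lapply(bounds, function(s) {
    Re(stats::fft(F * gauss_lowpass(f2, s), inverse = TRUE))[ri, ci] / length(F)
  })
  energy <- vapply(seq_along(scales), function(k) {
    band <- lowpassed[[k]] - lowpassed[[k + 1]]
    sd(band[mask$pixels])
  }, numeric(1))
  new_energy_spectrum(scales, energy, mult)
}

new_energy_spectrum <- function(scales, energy, multiplier) {
  out <- tibble::tibble(scale_px = as.numeric(scales), energy = energy)
  attr(out, "multiplier") <- multiplier
  class(out) <- c("energy_spectrum", class(out))
  out
}

check_spectrum <- function(x) {
  if (!is.data.frame(x) || !all(c("scale_px", "energy") %in% names(x))) {
    abort_chromatch("Expected an energy spectrum with columns scale_px, energy.",
                    "chromatch_shape_error")
  }
  invisible(x)
}

#' Dominant spatial scale of a spectrum
#'
#' The scale carrying the most pattern energy. Ties break toward the
#' smallest scale; an all-zero spectrum (featureless region) has no dominant
#' scale and raises an error.
#'
#' @param spectrum An [energy_spectrum()] tibble.
#' @return Scalar scale in pixels.
#' @export
dominant_scale <- function(spectrum) {
  check_spectrum(spectrum)
  if (nrow(spectrum) < 1L) {
    abort_chromatch("Empty spectrum.", "chromatch_empty_series_error")
  }
  if (all(spectrum$energy == 0)) {
    abort_chromatch("All-zero spectrum: dominant scale is undefined.",
                    "chromatch_undefined_dominant_scale_error")
  }
  spectrum$scale_px[which.max(spectrum$energy)]
}

#' Pattern distribution difference between two spectra
#'
#' Aggregate discrepancy in pattern energy across spatial scales: the sum
#' over scales of absolute energy differences. Zero means identical
#' patterning as seen by the bandpass decomposition; the measure is a
#' pseudometric (non-negative, symmetric, triangle inequality).
#'
#' @param a,b [energy_spectrum()] tibbles over the identical scale series.
#' @return Non-negative scalar.
#' @export
pattern_distribution_difference <- function(a, b) {
  check_spectrum(a); check_spectrum(b)
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$scale_px, b$scale_px))) {
    abort_chromatch("Spectra were measured on different scale series.",
                    "chromatch_incompatible_spectra_error")
  }
  sum(abs(a$energy - b$energy))
}

#' Animal-versus-background pattern metrics
#'
#' Summarizes how well an animal's patterning matches its background: the
#' background's dominant spatial scale, the animal-minus-background energy
#' difference at that scale, and the pattern distribution difference across
#' all scales.
#'
#' @param animal_spectrum,background_spectrum [energy_spectrum()] tibbles on
#'   a shared scale series.
#' @return A one-row tibble with `dominant_scale_px`,
#'   `energy_diff_at_dominant`, `pattern_distribution_difference`.
#' @export
pattern_metrics <- function(animal_spectrum, background_spectrum) {
  pdd <- pattern_distribution_difference(animal_spectrum, background_spectrum)
  dom <- dominant_scale(background_spectrum)
  k <- which(background_spectrum$scale_px == dom)
  tibble::tibble(
    dominant_scale_px = dom,
    energy_diff_at_dominant = animal_spectrum$energy[k] - background_spectrum$energy[k],
    pattern_distribution_difference = pdd
  )
}

#' Double-cone luminance image
#'
#' Applies the achromatic (double cone) row of a [catch_mapping()] pixelwise
#' to a reflectance image, yielding the single-band luminance raster the
#' pattern analysis consumes.
#'
#' @param image A [multiband_image()] in state `"reflectance"`.
#' @param mapping A [catch_mapping()] whose columns match the image bands.
#' @param achromatic Row name of the achromatic receptor.
#' @return A numeric matrix of double-cone catches.
#' @export
luminance_image <- function(image, mapping = default_catch_mapping(),
                            achromatic = "dbl") {
  stopifnot(inherits(image, "multiband_image"), inherits(mapping, "catch_mapping"))
  M <- mapping$matrix
  if (!achromatic %in% rownames(M)) {
    abort_chromatch("Achromatic receptor not found in the mapping.",
                    "chromatch_shape_error")
  }
  bands <- colnames(M)
  if (!setequal(bands, image$band_names)) {
    abort_chromatch("Mapping bands do not match the image bands.",
                    "chromatch_shape_error")
  }
  w <- M[achromatic, ]
  out <- matrix(0, dim(image$pixels)[1], dim(image$pixels)[2])
  for (b in bands) out <- out + w[[b]] * image$pixels[, , b]
  out
}
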