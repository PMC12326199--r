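#' Camera response specifications
#'
#' A response spec describes the (monotone increasing) mapping from scene
#' radiance to stored pixel value for one band, so that [linearize()] can
#' invert it. Synthetic images and pre-linearized exports are already linear,
#' so the default is the identity; a power-law (gamma) response is offered
#' for convenience, and arbitrary responses can be supplied as a
#' forward/inverse function pair.
#'
#' @param gamma Positive exponent of the forward response `v = gain * x^gamma`.
#' @param gain Positive multiplier.
#' @param forward,inverse Functions; `inverse(forward(x)) == x` must hold on
#'   the image's value range.
#' @return A `response_spec` object.
#' @export
response_identity <- function() {
  new_response_spec(identity, identity, "identity")
}

#' @rdname response_identity
#' @export
response_gamma <- function(gamma = 2.2, gain = 1) {
  stopifnot_scalar_positive(gamma, "gamma")
  stopifnot_scalar_positive(gain, "gain")
  force(gamma); force(gain)
  new_response_spec(
    forward = function(x) gain * x^gamma,
    inverse = function(v) (v / gain)^(1 / gamma),
    label = sprintf("gamma(%.3g, gain %.3g)", gamma, gain)
  )
}

#' @rdname response_identity
#' @export
response_function <- function(forward, inverse) {
  stopifnot(is.function(forward), is.function(inverse))
  new_response_spec(forward, inverse, "custom")
}

new_response_spec <- function(forward, inverse, label) {
  structure(list(forward = forward, inverse = inverse, label = label),
            class = "response_spec")
}

#' @export
print.response_spec <- function(x, ...) {
  cat(sprintf("<response_spec> %s\n", x$label))
  invisible(x)
}

check_monotone <- function(spec, lo, hi) {
  grid <- seq(max(lo, 1e-9), max(hi, lo + 1e-6), length.out = 64)
  v <- spec$forward(grid)
  if (anyNA(v) || any(diff(v) <= 0)) {
    abort_chromatch("Response spec is not monotone increasing on the image's value range.",
                    "chromatch_invalid_calibration_error")
  }
}

#' Linearize a raw image
#'
#' Maps every pixel of a raw-state image through the inverse of the camera
#' response, producing a linear-state image. Dimensions, band names and
#' spatial scale are unchanged. Each band may have its own response; a single
#' spec is recycled across bands.
#'
#' @param image A [multiband_image()] in state `"raw"`.
#' @param response A `response_spec` (see [response_identity()]) or a list of
#'   one spec per band.
#' @return A [multiband_image()] in state `"linear"`.
#' @export
#' @examples
#' img <- multiband_image(array(4, c(2, 2, 1)), "lum")
#' linearize(img, response_gamma(gamma = 2, gain = 1))$pixels[1, 1, 1] # 2
linearize <- function(image, response = response_identity()) {
  stopifnot(inherits(image, "multiband_image"))
  if (image$state != "raw") {
    abort_chromatch("`linearize()` expects an image in state 'raw'.",
                    "chromatch_invalid_calibration_error")
  }
  nb <- length(image$band_names)
  specs <- if (inherits(response, "response_spec")) {
    rep(list(response), nb)
  } else if (is.list(response) && length(response) == nb &&
             all(vapply(response, inherits, TRUE, "response_spec"))) {
    response
  } else {
    abort_chromatch("`response` must be a response_spec or a list of one per band.",
                    "chromatch_invalid_calibration_error")
  }
  px <- image$pixels
  for (b in seq_len(nb)) {
    band <- px[, , b]
    check_monotone(specs[[b]], min(band), max(band))
    px[, , b] <- specs[[b]]$inverse(band)
  }
  multiband_image(px, image$band_names, image$px_per_mm, state = "linear")
}

#' Normalize a linear image to reflectance
#'
#' Per band, fits the two-point affine map sending the dark standard's
#' measured value to its known reflectance and the bright standard's to its,
#' and applies it to every pixel. Values driven below zero by the affine map
#' are clipped to zero; values above one (specular highlights) are kept and
#' reported via a warning.
#'
#' @param image A [multiband_image()] in state `"linear"`.
#' @param standards A [grey_standard_pair()] whose measured vectors have one
#'   entry per band (scalars are recycled).
#' @return A [multiband_image()] in state `"reflectance"`.
#' @export
normalize_to_reflectance <- function(image, standards) {
  stopifnot(inherits(image, "multiband_image"),
            inherits(standards, "grey_standard_pair"))
  if (image$state != "linear") {
    abort_chromatch("`normalize_to_reflectance()` expects an image in state 'linear'.",
                    "chromatch_invalid_calibration_error")
  }
  nb <- length(image$band_names)
  lo <- rep_len(standards$measured_low, nb)
  hi <- rep_len(standards$measured_high, nb)
  if (any(lo >= hi)) {
    abort_chromatch("Degenerate standards: dark >= bright in some band.",
                    "chromatch_degenerate_standards_error")
  }
  px <- image$pixels
  n_over <- 0L
  for (b in seq_len(nb)) {
    slope <- (standards$reflectance_high - standards$reflectance_low) / (hi[b] - lo[b])
    refl <- standards$reflectance_low + (px[, , b] - lo[b]) * slope
    n_over <- n_over + sum(refl > 1)
    px[, , b] <- pmax(refl, 0)
  }
  if (n_over > 0L) {
    warning(sprintf("%d pixel(s) exceed reflectance 1 (specular highlights?); kept as-is.",
                    n_over), call. = FALSE)
  }
  multiband_image(px, image$band_names, image$px_per_mm, state = "reflectance")
}

#' Mean band values inside an ROI
#'
#' Arithmetic mean of each band over the masked pixels, the per-image summary
#' every downstream comparison consumes.
#'
#' @param image A [multiband_image()].
#' @param mask A [roi_mask()] with the same raster dimensions.
#' @return A named numeric vector, one mean per band, in band order.
#' @export
extract_roi_mean <- function(image, mask) {
  stopifnot(inherits(image, "multiband_image"), inherits(mask, "roi_mask"))
  check_mask_matches(image, mask)
  nb <- length(image$band_names)
  out <- vapply(seq_len(nb), function(b) mean(image$pixels[, , b][mask$pixels]),
                numeric(1))
  setNames(out, image$band_names)
}
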