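#' Multiband image container
#'
#' A `multiband_image` holds a stack of co-registered single-band rasters
#' (height x width x band array), the band names, the spatial scale in pixels
#' per millimetre, and a calibration `state`. The state machine is strict:
#' images start `"raw"` (camera counts), become `"linear"` after
#' [linearize()], and `"reflectance"` after [normalize_to_reflectance()].
#' Pixel coordinates are 0-based, row-major, origin at the top-left corner.
#'
#' @param pixels Numeric array `height x width x n_bands` (a matrix is
#'   accepted for a single band) of non-negative values.
#' @param band_names Character vector naming the bands, one per slice.
#' @param px_per_mm Positive spatial scale. The study convention is 18 px/mm.
#' @param state One of `"raw"`, `"linear"`, `"reflectance"`.
#'
#' @return A `multiband_image` object.
#' @export
#' @examples
#' img <- multiband_image(array(0.5, c(4, 4, 3)), c("sw", "mw", "lw"))
#' dim(img$pixels)
multiband_image <- function(pixels, band_names, px_per_mm = 18, state = "raw") {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, c(dim(pixels), 1L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    abort_chromatch("`pixels` must be a height x width x band array.",
                    "chromatch_shape_error")
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    abort_chromatch("Pixel values must be non-negative and non-missing.",
                    "chromatch_domain_error")
  }
  band_names <- as.character(band_names)
  if (length(band_names) != dim(pixels)[3]) {
    abort_chromatch("`band_names` length must match the number of band slices.",
                    "chromatch_shape_error")
  }
  stopifnot_scalar_positive(px_per_mm, "px_per_mm")
  state <- match.arg(state, c("raw", "linear", "reflectance"))
  dimnames(pixels) <- NULL
  structure(
    list(pixels = pixels, band_names = band_names,
         px_per_mm = px_per_mm, state = state),
    class = "multiband_image"
  )
}

#' @export
print.multiband_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<multiband_image> %d x %d px, %d band(s) [%s], %.3g px/mm, state: %s\n",
              d[1], d[2], d[3], paste(x$band_names, collapse = ", "),
              x$px_per_mm, x$state))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A binary raster marking the pixels belonging to one region of interest
#' (e.g. an animal's flank, or a patch of background). Any nonzero value is
#' inside the ROI.
#'
#' @param pixels Logical or numeric matrix; nonzero/`TRUE` marks the ROI.
#'
#' @return A `roi_mask` object with fields `pixels` (logical matrix) and
#'   `n_pixels`.
#' @export
roi_mask <- function(pixels) {
  if (!is.matrix(pixels)) {
    abort_chromatch("`pixels` must be a matrix.", "chromatch_shape_error")
  }
  px <- if (is.logical(pixels)) pixels else pixels != 0
  n <- sum(px)
  if (n < 1L) {
    abort_chromatch("ROI mask is empty: at least one pixel must be inside.",
                    "chromatch_empty_roi_error")
  }
  structure(list(pixels = px, n_pixels = n), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d inside\n",
              nrow(x$pixels), ncol(x$pixels), x$n_pixels))
  invisible(x)
}

check_mask_matches <- function(image, mask) {
  d <- dim(image$pixels)
  if (!identical(dim(mask$pixels), d[1:2])) {
    abort_chromatch("Mask dimensions do not match the image.",
                    "chromatch_shape_error")
  }
}

#' Grey reflectance standard pair
#'
#' Two diffuse grey standards of known reflectance photographed under the
#' same lighting as the subject anchor the affine map from linear camera
#' values to reflectance. The study used standards of 8.6% and 95.8%
#' reflectance.
#'
#' @param measured_low,measured_high Per-band mean pixel values of the dark
#'   and bright standards in the (linearized) image.
#' @param reflectance_low,reflectance_high Known reflectances in (0, 1).
#'
#' @return A `grey_standard_pair` object.
#' @export
grey_standard_pair <- function(measured_low, measured_high,
                               reflectance_low = 0.086,
                               reflectance_high = 0.958) {
  for (r in c(reflectance_low, reflectance_high)) {
    if (!is_scalar_number(r) || r <= 0 || r >= 1) {
      abort_chromatch("Standard reflectances must lie strictly in (0, 1).",
                      "chromatch_domain_error")
    }
  }
  if (reflectance_low >= reflectance_high) {
    abort_chromatch("`reflectance_low` must be below `reflectance_high`.",
                    "chromatch_degenerate_standards_error")
  }
  if (length(measured_low) != length(measured_high)) {
    abort_chromatch("Measured standard vectors must have equal length.",
                    "chromatch_shape_error")
  }
  if (any(!is.finite(measured_low)) || any(!is.finite(measured_high))) {
    abort_chromatch("Measured standard values must be finite.",
                    "chromatch_domain_error")
  }
  if (any(measured_low >= measured_high)) {
    abort_chromatch(
      "Dark standard measures at or above bright standard in some band; calibration is degenerate.",
      "chromatch_degenerate_standards_error")
  }
  structure(
    list(measured_low = measured_low, measured_high = measured_high,
         reflectance_low = reflectance_low, reflectance_high = reflectance_high),
    class = "grey_standard_pair"
  )
}

#' Read and write multiband images
#'
#' Images travel as multi-channel TIFF (preferred, written 16-bit) or PNG.
#' Neither container names its channels, so band names, spatial scale and
#' calibration state ride in a YAML sidecar (`<image>.yml`) written and read
#' alongside the raster.
#'
#' @param image A [multiband_image()].
#' @param path File path ending in `.tif`, `.tiff` or `.png`. Pixel values
#'   must lie in \[0, 1\] for these containers.
#' @return `write_multiband()` returns `path` invisibly; `read_multiband()`
#'   returns a [multiband_image()].
#' @export
write_multiband <- function(image, path) {
  stopifnot(inherits(image, "multiband_image"))
  px <- image$pixels
  if (max(px) > 1) {
    abort_chromatch("TIFF/PNG containers require pixel values in [0, 1]; rescale first.",
                    "chromatch_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(px, path)
  } else {
    abort_chromatch("Unsupported image extension; use .tif/.tiff/.png.",
                    "chromatch_io_error")
  }
  yaml::write_yaml(
    list(band_names = as.list(image$band_names),
         px_per_mm = image$px_per_mm, state = image$state),
    sidecar_path(path))
  invisible(path)
}

#' @rdname write_multiband
#' @export
read_multiband <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    abort_chromatch("Unsupported image extension; use .tif/.tiff/.png.",
                    "chromatch_io_error")
  }
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  meta <- sidecar_path(path)
  if (file.exists(meta)) {
    info <- yaml::read_yaml(meta)
    multiband_image(px, unlist(info$band_names),
                    px_per_mm = info$px_per_mm, state = info$state)
  } else {
    multiband_image(px, paste0("band", seq_len(dim(px)[3])))
  }
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yml")

#' Read and write ROI masks
#'
#' Masks are exchanged as single-band PNG (or TIFF) rasters in which any
#' nonzero pixel is inside the ROI.
#'
#' @param mask A [roi_mask()].
#' @param path File path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` a
#'   [roi_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  ext <- tolower(tools::file_ext(path))
  m <- mask$pixels * 1
  if (ext == "png") png::writePNG(m, path) else tiff::writeTIFF(m, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  roi_mask(m > 0)
}
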