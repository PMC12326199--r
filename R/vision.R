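#' Predator receptor set
#'
#' Describes the receiver's photoreceptor classes: the chromatic single
#' cones (with relative abundances that set channel noise) and the double
#' cone assumed to mediate achromatic vision in birds. The default is a
#' violet-sensitive trichromat (UV excluded) with a reference Weber fraction
#' of 0.05 assigned to the most abundant chromatic class, the convention of
#' the receptor-noise-limited discrimination model.
#'
#' The default relative abundances of the short-, medium- and long-wave
#' single cones (1.9, 2.2, 2.1) are implementer-supplied values drawn from
#' published peafowl retinal data; they are configuration, not measurements
#' from any one study, and can be replaced freely.
#'
#' @param names Receptor labels; the last is the achromatic (double cone)
#'   class unless `achromatic` says otherwise.
#' @param relative_abundance Positive relative abundances of the chromatic
#'   classes, named or in `names` order.
#' @param weber_reference Weber fraction of the most abundant chromatic
#'   class, in (0, 1).
#' @param achromatic_weber Weber fraction of the double-cone channel, in (0, 1).
#' @param achromatic Name of the achromatic receptor.
#' @return A `receptor_set` object.
#' @export
#' @examples
#' receptor_set()
receptor_set <- function(names = c("sw", "mw", "lw", "dbl"),
                         relative_abundance = c(sw = 1.9, mw = 2.2, lw = 2.1),
                         weber_reference = 0.05,
                         achromatic_weber = 0.05,
                         achromatic = "dbl") {
  names <- as.character(names)
  if (!achromatic %in% names) {
    abort_chromatch("`achromatic` must be one of `names`.", "chromatch_domain_error")
  }
  chromatic <- setdiff(names, achromatic)
  if (length(chromatic) < 2L) {
    abort_chromatch("At least two chromatic receptor classes are required.",
                    "chromatch_domain_error")
  }
  if (is.null(base::names(relative_abundance))) {
    if (length(relative_abundance) != length(chromatic)) {
      abort_chromatch("`relative_abundance` must have one entry per chromatic receptor.",
                      "chromatch_shape_error")
    }
    relative_abundance <- setNames(relative_abundance, chromatic)
  }
  if (!setequal(base::names(relative_abundance), chromatic)) {
    abort_chromatch("`relative_abundance` names must match the chromatic receptors.",
                    "chromatch_shape_error")
  }
  relative_abundance <- relative_abundance[chromatic]
  if (any(!is.finite(relative_abundance)) || any(relative_abundance <= 0)) {
    abort_chromatch("Relative abundances must be positive and finite.",
                    "chromatch_domain_error")
  }
  for (w in c(weber_reference, achromatic_weber)) {
    if (!is_scalar_number(w) || w <= 0 || w >= 1) {
      abort_chromatch("Weber fractions must lie strictly in (0, 1).",
                      "chromatch_domain_error")
    }
  }
  structure(
    list(names = names, chromatic = chromatic, achromatic = achromatic,
         relative_abundance = relative_abundance,
         weber_reference = weber_reference,
         achromatic_weber = achromatic_weber),
    class = "receptor_set"
  )
}

#' @export
print.receptor_set <- function(x, ...) {
  cat(sprintf("<receptor_set> chromatic: %s | achromatic: %s\n",
              paste(x$chromatic, collapse = ", "), x$achromatic))
  cat("  abundances:", paste(sprintf("%s=%.3g", names(x$relative_abundance),
                                     x$relative_abundance), collapse = ", "), "\n")
  cat(sprintf("  Weber: %.3g (reference), %.3g (achromatic)\n",
              x$weber_reference, x$achromatic_weber))
  invisible(x)
}

#' Per-channel Weber fractions
#'
#' Channel noise under the receptor-noise-limited model scales with the
#' inverse square root of receptor abundance:
#' `e_i = w * sqrt(eta_ref / eta_i)`, where `eta_ref` is the largest relative
#' abundance, so the most abundant chromatic class carries exactly the
#' reference Weber fraction `w`.
#'
#' @param receptors A [receptor_set()].
#' @return Named numeric vector of Weber fractions, one per chromatic class.
#' @export
#' @examples
#' weber_fractions(receptor_set(relative_abundance = c(sw = 1, mw = 2, lw = 2)))
weber_fractions <- function(receptors) {
  stopifnot(inherits(receptors, "receptor_set"))
  eta <- receptors$relative_abundance
  receptors$weber_reference * sqrt(max(eta) / eta)
}

#' Camera-band to receptor catch mapping
#'
#' A non-negative matrix sending per-band reflectances to receptor quantum
#' catches, `q = M %*% band_means`. The default, for three chromatic bands
#' named like the receptors, is the identity on the chromatic classes with a
#' double-cone row equal to the mean of the two longer-wavelength bands.
#'
#' @param matrix Numeric matrix, receptors x bands, row names = receptor
#'   names, column names = band names.
#' @return A `catch_mapping` object.
#' @export
catch_mapping <- function(matrix) {
  if (!is.matrix(matrix) || anyNA(matrix) || any(matrix < 0)) {
    abort_chromatch("`matrix` must be a non-negative numeric matrix.",
                    "chromatch_domain_error")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    abort_chromatch("Mapping rows (receptors) and columns (bands) must be named.",
                    "chromatch_shape_error")
  }
  if (any(rowSums(matrix) <= 0)) {
    abort_chromatch("Every receptor row needs at least one positive entry.",
                    "chromatch_domain_error")
  }
  structure(list(matrix = matrix), class = "catch_mapping")
}

#' @rdname catch_mapping
#' @param bands Band names for the default mapping.
#' @param receptors A [receptor_set()] supplying receptor names.
#' @export
default_catch_mapping <- function(bands = c("sw", "mw", "lw"),
                                  receptors = receptor_set()) {
  chrom <- receptors$chromatic
  if (length(bands) != length(chrom)) {
    abort_chromatch("Default mapping expects one band per chromatic receptor.",
                    "chromatch_shape_error")
  }
  m <- diag(length(chrom))
  rownames(m) <- chrom
  colnames(m) <- bands
  # double cone integrates the two longest-wavelength bands
  dbl <- matrix(0, 1, length(bands), dimnames = list(receptors$achromatic, bands))
  long2 <- tail(seq_along(bands), 2)
  dbl[1, long2] <- 0.5
  catch_mapping(rbind(m, dbl))
}

#' @export
print.catch_mapping <- function(x, ...) {
  cat("<catch_mapping>\n")
  print(x$matrix)
  invisible(x)
}

#' Receptor quantum catches from band means
#'
#' Applies a [catch_mapping()] to per-band (reflectance) means, yielding one
#' quantum catch per receptor class. Catches of exactly zero are rejected:
#' the log-ratio discrimination model downstream cannot consume them, so the
#' caller must floor or exclude such regions.
#'
#' @param band_means Named non-negative numeric vector of per-band means, in
#'   the mapping's column order (names are checked when present).
#' @param mapping A [catch_mapping()].
#' @return Named numeric vector of quantum catches, one per receptor.
#' @export
#' @examples
#' m <- default_catch_mapping()
#' catches_from_bands(c(sw = 0.2, mw = 0.4, lw = 0.6), m)
catches_from_bands <- function(band_means, mapping = default_catch_mapping()) {
  stopifnot(inherits(mapping, "catch_mapping"))
  M <- mapping$matrix
  if (length(band_means) != ncol(M)) {
    abort_chromatch("`band_means` length must match the mapping's bands.",
                    "chromatch_shape_error")
  }
  if (!is.null(names(band_means))) {
    if (!setequal(names(band_means), colnames(M))) {
      abort_chromatch("`band_means` names do not match the mapping's bands.",
                      "chromatch_shape_error")
    }
    band_means <- band_means[colnames(M)]
  }
  if (any(!is.finite(band_means)) || any(band_means < 0)) {
    abort_chromatch("Band means must be finite and non-negative.",
                    "chromatch_domain_error")
  }
  q <- drop(M %*% band_means)
  if (any(q == 0)) {
    abort_chromatch(
      paste0("Zero quantum catch in receptor(s): ",
             paste(rownames(M)[q == 0], collapse = ", "),
             ". Floor the input or exclude the region."),
      "chromatch_zero_catch_error")
  }
  setNames(q, rownames(M))
}
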