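#' Chromatic just-noticeable difference (receptor-noise-limited model)
#'
#' Colour distance between two stimuli for a trichromatic receiver whose
#' discrimination is limited by independent noise in each receptor channel.
#' With log-transformed catch contrasts `df_i = ln(qA_i / qB_i)` and channel
#' Weber fractions `e_i`, the distance in just-noticeable-difference (JND)
#' units is
#'
#' \deqn{\Delta S = \sqrt{\frac{e_1^2 (df_3 - df_2)^2 + e_2^2 (df_3 - df_1)^2
#'   + e_3^2 (df_1 - df_2)^2}{(e_1 e_2)^2 + (e_1 e_3)^2 + (e_2 e_3)^2}}}
#'
#' Values below about 1 JND are indistinguishable to the receiver. The
#' trichromatic form is deliberate: dichromat or tetrachromat inputs are
#' rejected rather than silently generalized.
#'
#' @param qA,qB Positive numeric vectors of three chromatic quantum catches.
#' @param e Positive numeric vector of three channel Weber fractions.
#' @return Non-negative scalar, in JND units.
#' @export
#' @examples
#' chromatic_jnd(c(1, 1, exp(0.05)), c(1, 1, 1), e = rep(0.05, 3)) # sqrt(2/3)
chromatic_jnd <- function(qA, qB, e) {
  if (length(qA) != 3L || length(qB) != 3L) {
    abort_chromatch("The receptor-noise model here is trichromatic: exactly 3 chromatic catches.",
                    "chromatch_unsupported_dimension_error")
  }
  if (length(e) != 3L) {
    abort_chromatch("Exactly 3 channel Weber fractions are required.",
                    "chromatch_unsupported_dimension_error")
  }
  check_positive_catches(c(qA, qB))
  if (any(!is.finite(e)) || any(e <= 0)) {
    abort_chromatch("Weber fractions must be positive and finite.",
                    "chromatch_domain_error")
  }
  df <- log(qA / qB)
  num <- e[1]^2 * (df[3] - df[2])^2 +
         e[2]^2 * (df[3] - df[1])^2 +
         e[3]^2 * (df[1] - df[2])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  sqrt(num / den)
}

#' Achromatic just-noticeable difference
#'
#' Luminance distance carried by the double-cone channel: the absolute
#' log-ratio of the two double-cone catches divided by that channel's Weber
#' fraction.
#'
#' @param qA_dbl,qB_dbl Positive double-cone quantum catches.
#' @param w_dbl Double-cone Weber fraction in (0, 1); the study convention
#'   is 0.05.
#' @return Non-negative scalar, in JND units.
#' @export
#' @examples
#' achromatic_jnd(1.1, 1.0) # ln(1.1)/0.05 = 1.906
achromatic_jnd <- function(qA_dbl, qB_dbl, w_dbl = 0.05) {
  check_positive_catches(c(qA_dbl, qB_dbl))
  if (!is_scalar_number(w_dbl) || w_dbl <= 0 || w_dbl >= 1) {
    abort_chromatch("`w_dbl` must lie strictly in (0, 1).", "chromatch_domain_error")
  }
  abs(log(qA_dbl / qB_dbl)) / w_dbl
}

check_positive_catches <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) {
    abort_chromatch("Quantum catches must be strictly positive and finite.",
                    "chromatch_domain_error")
  }
  invisible(q)
}

#' Compare two regions of interest in JND units
#'
#' Takes full catch samples (chromatic classes plus double cone) for an
#' animal region and a background region and returns both discrimination
#' distances: the chromatic receptor-noise-limited JND and the achromatic
#' double-cone JND.
#'
#' @param animal,background Named numeric vectors of quantum catches covering
#'   every receptor in `receptors`.
#' @param receptors A [receptor_set()].
#' @return A one-row tibble with columns `chromatic_jnd`, `achromatic_jnd`,
#'   `weber_used`.
#' @export
#' @examples
#' r <- receptor_set()
#' compare_rois(c(sw = .2, mw = .4, lw = .6, dbl = .5),
#'              c(sw = .2, mw = .4, lw = .6, dbl = .25), r)
compare_rois <- function(animal, background, receptors = receptor_set()) {
  stopifnot(inherits(receptors, "receptor_set"))
  for (q in list(animal, background)) {
    if (is.null(names(q)) || !all(receptors$names %in% names(q))) {
      abort_chromatch("Catch samples must be named and cover every receptor in the set.",
                      "chromatch_shape_error")
    }
  }
  chrom <- receptors$chromatic
  if (length(chrom) != 3L) {
    abort_chromatch("The chromatic comparison is trichromatic-only.",
                    "chromatch_unsupported_dimension_error")
  }
  e <- weber_fractions(receptors)
  tibble::tibble(
    chromatic_jnd = chromatic_jnd(unname(animal[chrom]), unname(background[chrom]),
                                  e = unname(e[chrom])),
    achromatic_jnd = achromatic_jnd(animal[[receptors$achromatic]],
                                    background[[receptors$achromatic]],
                                    w_dbl = receptors$achromatic_weber),
    weber_used = receptors$weber_reference
  )
}

#' Append JND columns to a table of paired catch samples
#'
#' Batch interface over [compare_rois()]: each row holds the animal and
#' background catches for one observation, in columns named
#' `<animal_prefix><receptor>` and `<background_prefix><receptor>`. The input
#' is returned with `chromatic_jnd` and `achromatic_jnd` appended, ready to
#' pipe into the trend models.
#'
#' @param data A data frame.
#' @param receptors A [receptor_set()].
#' @param animal_prefix,background_prefix Column-name prefixes.
#' @return `data` as a tibble with two JND columns appended.
#' @export
jnd_table <- function(data, receptors = receptor_set(),
                      animal_prefix = "animal_", background_prefix = "bg_") {
  data <- tibble::as_tibble(data)
  a_cols <- paste0(animal_prefix, receptors$names)
  b_cols <- paste0(background_prefix, receptors$names)
  missing <- setdiff(c(a_cols, b_cols), names(data))
  if (length(missing)) {
    abort_chromatch(paste0("Missing catch columns: ", paste(missing, collapse = ", ")),
                    "chromatch_shape_error")
  }
  res <- purrr::map2_dfr(
    split(as.matrix(data[a_cols]), seq_len(nrow(data))),
    split(as.matrix(data[b_cols]), seq_len(nrow(data))),
    function(a, b) {
      compare_rois(setNames(a, receptors$names), setNames(b, receptors$names),
                   receptors)[, c("chromatic_jnd", "achromatic_jnd")]
    })
  dplyr::bind_cols(data, res)
}
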