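#' Treatment vocabulary and background palette
#'
#' The experimental design exposes animals to 13 backgrounds: four uniform
#' hues (yellow, yellow-green, orange, blue-green), three uniform greyscale
#' levels (black, white, grey — the greyscale trio shares chromatic ratios
#' and differs only in brightness), and six patterned backgrounds (black and
#' white, or green and yellow, as random square-patch mosaics at three patch
#' sizes). `treatment_vocabulary()` lists the labels;
#' `background_palette()` maps a label to its per-band reflectances, patch
#' size, and (for patterned treatments) the two component colours. The
#' specific reflectance triplets and the 16 / 45 / 128 px patch edge lengths
#' are package configuration chosen to be colourful-but-plausible; patterned
#' backgrounds use the mean of their two components as the effective
#' comparison colour.
#'
#' @param treatment A treatment label.
#' @return `background_palette()` returns a list with `bands` (named sw/mw/lw
#'   reflectances), `type`, `family`, `patch_px` (NA for uniform), and
#'   `components` (two-row matrix for patterned treatments, else NULL).
#' @export
treatment_vocabulary <- function() {
  c("yellow", "yellow-green", "orange", "blue-green",
    "grey", "black", "white",
    "black-white-small", "black-white-medium", "black-white-large",
    "green-yellow-small", "green-yellow-medium", "green-yellow-large")
}

uniform_palette <- function() {
  # yellow-green and blue-green sit close to the resting animal colour
  # (starting chromatic JND < 3); yellow and orange are strong mismatches
  list(
    "yellow"       = c(sw = 0.08, mw = 0.55, lw = 0.70),
    "yellow-green" = c(sw = 0.135, mw = 0.44, lw = 0.385),
    "orange"       = c(sw = 0.06, mw = 0.25, lw = 0.65),
    "blue-green"   = c(sw = 0.175, mw = 0.42, lw = 0.315),
    "grey"         = c(sw = 0.40, mw = 0.40, lw = 0.40),
    "black"        = c(sw = 0.05, mw = 0.05, lw = 0.05),
    "white"        = c(sw = 0.90, mw = 0.90, lw = 0.90)
  )
}

patch_sizes_px <- function() c(small = 16, medium = 45, large = 128)

#' @rdname treatment_vocabulary
#' @export
background_palette <- function(treatment) {
  vocab <- treatment_vocabulary()
  if (!is.character(treatment) || length(treatment) != 1L || !treatment %in% vocab) {
    abort_chromatch(
      paste0("Unknown treatment '", treatment, "'. Known: ",
             paste(vocab, collapse = ", ")),
      "chromatch_vocabulary_error")
  }
  uni <- uniform_palette()
  if (treatment %in% names(uni)) {
    family <- if (treatment %in% c("grey", "black", "white")) "greyscale" else "colour"
    return(list(treatment = treatment, type = "uniform", family = family,
                bands = uni[[treatment]], patch_px = NA_real_, components = NULL))
  }
  parts <- strsplit(treatment, "-")[[1]]
  size <- parts[length(parts)]
  fam <- paste(parts[-length(parts)], collapse = "-")
  comp <- if (fam == "black-white") {
    rbind(uni[["black"]], uni[["white"]])
  } else {
    rbind(uni[["yellow"]], uni[["yellow-green"]])
  }
  rownames(comp) <- NULL
  list(treatment = treatment, type = "pattern", family = fam,
       bands = colMeans(comp), patch_px = unname(patch_sizes_px()[size]),
       components = comp)
}

#' Resting animal coloration
#'
#' Per-band reflectances of the simulated animal's flank at rest: a muted
#' green-brown, the generic coloration the analysis assumes animals start
#' from before any background-driven change.
#'
#' @return Named numeric vector of sw/mw/lw reflectances.
#' @export
baseline_animal_bands <- function() c(sw = 0.15, mw = 0.40, lw = 0.35)

default_approach_rates <- function() {
  # per-minute exponential approach rates toward the background colour,
  # calibrated so the default experiment shows minutes-scale dynamics of the
  # magnitude reported for this kind of assay: strongest change on yellow
  # and black, moderate on orange and white, weak where the animal already
  # matches, zero on the grey control
  c("yellow" = 0.003, "yellow-green" = 0.002, "orange" = 0.002,
    "blue-green" = 0.002, "grey" = 0, "black" = 0.015, "white" = 0.008,
    "black-white-small" = 0.002, "black-white-medium" = 0.002,
    "black-white-large" = 0.002, "green-yellow-small" = 0.002,
    "green-yellow-medium" = 0.002, "green-yellow-large" = 0.002)
}

#' Synthetic experiment configuration
#'
#' Bundles every knob of the synthetic colour-change experiment: the number
#' of individuals, the treatments, the two photographic time grids (a long
#' first trial at 0, 1, 3 and then 3-minute intervals to 21 min; a short
#' second trial at 0, 1, 3, 6, 9 min run for colour treatments only), the
#' per-treatment exponential approach rate toward the background colour, the
#' individual-level random variation, the multiplicative measurement noise,
#' and the seed (mandatory: every simulation is reproducible by
#' construction).
#'
#' @param n_individuals Number of simulated animals.
#' @param treatments Subset of [treatment_vocabulary()].
#' @param time_points_min List with components `trial1` and `trial2`, each a
#'   strictly increasing vector of minutes.
#' @param approach_rate Named per-minute rates (lambda >= 0) toward the
#'   background, recycled from the defaults for treatments not named.
#' @param individual_sd SD (log scale) of per-individual multiplicative
#'   deviations in band reflectance.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise per band and observation.
#' @param seed Integer RNG seed (required).
#' @param img_height,img_width Rendered image size in pixels.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(n_individuals = 10,
                              treatments = treatment_vocabulary(),
                              time_points_min = list(
                                trial1 = c(0, 1, 3, 6, 9, 12, 15, 18, 21),
                                trial2 = c(0, 1, 3, 6, 9)),
                              approach_rate = default_approach_rates(),
                              individual_sd = 0.10,
                              noise_cv = 0.05,
                              seed,
                              img_height = 96, img_width = 160) {
  if (missing(seed) || !is_scalar_number(seed)) {
    abort_chromatch("`seed` is required for reproducible simulation.",
                    "chromatch_validation_error")
  }
  stopifnot_scalar_positive(n_individuals, "n_individuals")
  bad <- setdiff(treatments, treatment_vocabulary())
  if (length(bad)) {
    abort_chromatch(paste0("Unknown treatment(s): ", paste(bad, collapse = ", ")),
                    "chromatch_vocabulary_error")
  }
  for (grid in time_points_min) {
    if (any(grid < 0) || is.unsorted(grid, strictly = TRUE)) {
      abort_chromatch("Time points must be non-negative and strictly increasing.",
                      "chromatch_validation_error")
    }
  }
  lam <- default_approach_rates()
  lam[names(approach_rate)] <- approach_rate
  if (any(!is.finite(lam)) || any(lam < 0)) {
    abort_chromatch("Approach rates must be finite and >= 0.",
                    "chromatch_validation_error")
  }
  if (individual_sd < 0 || noise_cv < 0) {
    abort_chromatch("`individual_sd` and `noise_cv` must be >= 0.",
                    "chromatch_validation_error")
  }
  structure(
    list(n_individuals = as.integer(n_individuals), treatments = treatments,
         time_points_min = time_points_min, approach_rate = lam,
         individual_sd = individual_sd, noise_cv = noise_cv,
         seed = as.integer(seed),
         img_height = img_height, img_width = img_width),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %d individuals x %d treatments, seed %d\n",
              x$n_individuals, length(x$treatments), x$seed))
  cat(sprintf("  noise_cv %.3g, individual_sd %.3g\n", x$noise_cv, x$individual_sd))
  invisible(x)
}

#' Simulate one colour trajectory
#'
#' The simulated animal's per-receptor reflectance relaxes exponentially
#' from its starting value toward the background:
#' `q_i(t) = bg_i + (q_i(0) - bg_i) * exp(-lambda * t)`. Observations
#' multiply the mean by mean-one lognormal noise with coefficient of
#' variation `noise_cv`. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param baseline,background Positive numeric vectors (same length) of
#'   starting and background values per band/receptor.
#' @param lambda Approach rate per minute (>= 0).
#' @param times Ordered non-negative times in minutes.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @return Matrix `length(times) x length(baseline)`, rows named by time.
#' @export
#' @examples
#' simulate_trajectory(1, 2, lambda = 0.1, times = 10) # 2 - exp(-1) = 1.632
simulate_trajectory <- function(baseline, background, lambda, times,
                                noise_cv = 0) {
  if (length(baseline) != length(background)) {
    abort_chromatch("`baseline` and `background` must have equal length.",
                    "chromatch_shape_error")
  }
  if (any(baseline <= 0) || any(background <= 0)) {
    abort_chromatch("Baseline and background values must be positive.",
                    "chromatch_domain_error")
  }
  if (!is_scalar_number(lambda) || lambda < 0) {
    abort_chromatch("`lambda` must be a finite rate >= 0.", "chromatch_domain_error")
  }
  if (is.unsorted(times) || any(times < 0)) {
    abort_chromatch("`times` must be ordered and non-negative.",
                    "chromatch_domain_error")
  }
  decay <- exp(-lambda * times)
  mean_traj <- outer(decay, baseline - background) +
    matrix(background, length(times), length(background), byrow = TRUE)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(stats::rlnorm(length(mean_traj), -sdlog^2 / 2, sdlog),
                    nrow = nrow(mean_traj))
    mean_traj <- mean_traj * noise
  }
  rownames(mean_traj) <- as.character(times)
  colnames(mean_traj) <- names(baseline)
  mean_traj
}

trial_grids_for <- function(config, treatment) {
  pal <- background_palette(treatment)
  if (pal$type == "uniform" && pal$family == "colour") {
    list(`1` = config$time_points_min$trial1, `2` = config$time_points_min$trial2)
  } else {
    list(`1` = config$time_points_min$trial1)
  }
}

#' Generate record-level synthetic trials
#'
#' Fast path that bypasses image rendering: simulates per-band catch
#' trajectories for every individual x treatment x trial x time point, then
#' runs them through the vision and discrimination modules exactly as
#' measured images would be, yielding the per-photograph record table the
#' trend models consume. Individuals get per-band multiplicative lognormal
#' intercepts (SD `individual_sd` on the log scale); observations get
#' multiplicative noise of coefficient of variation `noise_cv`.
#'
#' @param config An [experiment_config()].
#' @param receptors A [receptor_set()].
#' @param mapping A [catch_mapping()] from sw/mw/lw bands to receptors.
#' @return A list: `records` (tibble with `individual_id`, `trial`,
#'   `treatment`, `time_min`, `chromatic_jnd`, `achromatic_jnd`,
#'   `luminance`), and `truth` (tibble of realized per-individual baselines,
#'   backgrounds and rates).
#' @export
generate_records <- function(config, receptors = receptor_set(),
                             mapping = default_catch_mapping()) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  base_bands <- baseline_animal_bands()
  records <- list()
  truth <- list()
  for (tr in config$treatments) {
    pal <- background_palette(tr)
    bg_q <- catches_from_bands(pal$bands, mapping)
    lambda <- config$approach_rate[[tr]]
    grids <- trial_grids_for(config, tr)
    for (i in seq_len(config$n_individuals)) {
      id <- sprintf("ind%02d", i)
      ind_effect <- exp(stats::rnorm(length(base_bands), 0, config$individual_sd))
      baseline_i <- base_bands * ind_effect
      truth[[length(truth) + 1L]] <- tibble::tibble(
        individual_id = id, treatment = tr, lambda = lambda,
        baseline_sw = baseline_i[["sw"]], baseline_mw = baseline_i[["mw"]],
        baseline_lw = baseline_i[["lw"]],
        bg_sw = pal$bands[["sw"]], bg_mw = pal$bands[["mw"]],
        bg_lw = pal$bands[["lw"]])
      for (trial in names(grids)) {
        times <- grids[[trial]]
        traj <- simulate_trajectory(baseline_i, pal$bands, lambda, times,
                                    noise_cv = config$noise_cv)
        jnds <- purrr::map_dfr(seq_along(times), function(k) {
          q_animal <- catches_from_bands(pmax(traj[k, ], 1e-6), mapping)
          out <- compare_rois(q_animal, bg_q, receptors)
          out$luminance <- q_animal[[receptors$achromatic]]
          out
        })
        records[[length(records) + 1L]] <- tibble::tibble(
          individual_id = id, trial = as.integer(trial), treatment = tr,
          time_min = times,
          chromatic_jnd = jnds$chromatic_jnd,
          achromatic_jnd = jnds$achromatic_jnd,
          luminance = jnds$luminance)
      }
    }
  }
  list(records = dplyr::bind_rows(records), truth = dplyr::bind_rows(truth))
}

#' Simulate records with known linear trends
#'
#' Gaussian generator with the exact statistical structure the trend models
#' assume: `response = intercept + b_individual [+ b_trial] + slope_j * time
#' + noise`. Used to validate slope recovery, confidence-limit coverage and
#' type-I error with a known truth.
#'
#' @param slopes Named numeric vector: true slope per treatment (response
#'   units per minute).
#' @param n_individuals Number of individuals.
#' @param intercept Grand intercept.
#' @param individual_sd,trial_sd,sigma SDs of the individual intercepts, the
#'   trial intercepts (0 drops the term), and the residual noise.
#' @param time_points_min List of trial time grids (as in
#'   [experiment_config()]); with `trial_sd = 0` only `trial1` is used.
#' @param seed Optional seed (leaves RNG untouched when NULL).
#' @return A tibble with `individual_id`, `trial`, `treatment`, `time_min`,
#'   `response`.
#' @export
simulate_trend_records <- function(slopes, n_individuals = 10,
                                   intercept = 5,
                                   individual_sd = 0.5, trial_sd = 0,
                                   sigma = 0.5,
                                   time_points_min = list(
                                     trial1 = c(0, 1, 3, 6, 9, 12, 15, 18, 21),
                                     trial2 = c(0, 1, 3, 6, 9)),
                                   seed = NULL) {
  if (is.null(names(slopes))) {
    names(slopes) <- paste0("t", seq_along(slopes))
  }
  if (!is.null(seed)) set.seed(seed)
  trials <- if (trial_sd > 0) names(time_points_min) else "trial1"
  b_trial <- setNames(rnorm(length(trials), 0, trial_sd), trials)
  rows <- list()
  for (i in seq_len(n_individuals)) {
    b_i <- rnorm(1, 0, individual_sd)
    for (tr in names(slopes)) {
      for (tri in trials) {
        times <- time_points_min[[tri]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          individual_id = sprintf("ind%02d", i),
          trial = match(tri, names(time_points_min)),
          treatment = tr, time_min = times,
          response = intercept + b_i + b_trial[[tri]] +
            slopes[[tr]] * times + rnorm(length(times), 0, sigma))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Render a random square-patch mosaic
#'
#' Fills a raster with square patches of edge `patch_px`, each patch drawn
#' uniformly from the rows of `components` (per-band colours). This is the
#' texture model for the patterned background treatments: its dominant
#' spatial scale is the patch size.
#'
#' @param height,width Raster size in pixels.
#' @param components Two-row (or more) matrix, one colour per row, columns =
#'   bands.
#' @param patch_px Patch edge length in pixels.
#' @return Array `height x width x n_bands`.
#' @export
render_mosaic <- function(height, width, components, patch_px) {
  stopifnot(is.matrix(components), nrow(components) >= 2)
  if (patch_px > min(height, width)) {
    abort_chromatch("Patch size exceeds the region extent.",
                    "chromatch_configuration_error")
  }
  nrp <- ceiling(height / patch_px)
  ncp <- ceiling(width / patch_px)
  pick <- matrix(sample.int(nrow(components), nrp * ncp, replace = TRUE), nrp, ncp)
  row_id <- pmin((seq_len(height) - 1) %/% patch_px + 1, nrp)
  col_id <- pmin((seq_len(width) - 1) %/% patch_px + 1, ncp)
  out <- array(0, c(height, width, ncol(components)))
  idx <- pick[cbind(rep(row_id, times = width), rep(col_id, each = height))]
  for (b in seq_len(ncol(components))) {
    out[, , b] <- matrix(components[idx, b], height, width)
  }
  out
}

#' Render a synthetic trial as calibrated-camera images
#'
#' Produces, for one individual under one treatment, a raw-state multiband
#' image per time point: a background region filled with the treatment
#' (uniform colour or patch mosaic), a rectangular animal region whose
#' colour follows [simulate_trajectory()], and two embedded grey-standard
#' patches of 8.6% and 95.8% reflectance, so the full
#' calibration-to-discrimination path can be exercised end to end. Raw pixel
#' values are reflectance mapped through a linear synthetic camera
#' (`gain * reflectance + offset`); the calibration module recovers
#' reflectance via the standards. Masks locate the animal, background, and
#' the two standards.
#'
#' @param config An [experiment_config()]. Image size comes from
#'   `img_height`/`img_width`; patterned treatments need a background large
#'   enough for their patch size.
#' @param treatment A treatment label.
#' @param individual Individual index (enters the ground truth and the id).
#' @param trial Which time grid to render (1 or 2).
#' @param animal_patch_px Optional patch size for a textured animal; NULL
#'   renders a uniform animal.
#' @param gain,offset Synthetic linear camera parameters.
#' @return A list: `images` (one raw [multiband_image()] per time point,
#'   named by minute), `masks` (list with `animal`, `background`,
#'   `standard_low`, `standard_high`), `standards_reflectance`, and `truth`
#'   (baseline/background bands and lambda).
#' @export
render_trial_images <- function(config, treatment, individual = 1, trial = 1,
                                animal_patch_px = NULL,
                                gain = 0.8, offset = 0.05) {
  stopifnot(inherits(config, "experiment_config"))
  pal <- background_palette(treatment)
  H <- config$img_height; W <- config$img_width
  geom <- trial_geometry(H, W)
  bg_extent <- min(H, W) # mosaic patches must fit the frame
  if (pal$type == "pattern" && pal$patch_px > bg_extent / 2) {
    abort_chromatch("Patch size exceeds the background extent; enlarge the image.",
                    "chromatch_configuration_error")
  }
  grids <- trial_grids_for(config, treatment)
  trial <- as.character(trial)
  if (!trial %in% names(grids)) {
    abort_chromatch("Requested trial has no time grid for this treatment.",
                    "chromatch_configuration_error")
  }
  times <- grids[[trial]]
  ind_effect <- exp(stats::rnorm(3, 0, config$individual_sd))
  baseline_i <- baseline_animal_bands() * ind_effect
  traj <- simulate_trajectory(baseline_i, pal$bands,
                              config$approach_rate[[treatment]], times,
                              noise_cv = config$noise_cv)
  bands <- c("sw", "mw", "lw")
  background_fill <- if (pal$type == "pattern") {
    render_mosaic(H, W, pal$components, pal$patch_px)
  } else {
    arr <- array(0, c(H, W, 3))
    for (b in 1:3) arr[, , b] <- pal$bands[[b]]
    arr
  }
  images <- lapply(seq_along(times), function(k) {
    refl <- background_fill
    a <- geom$animal
    if (is.null(animal_patch_px)) {
      for (b in 1:3) refl[a$rows, a$cols, b] <- traj[k, b]
    } else {
      # textured animal: mosaic of the animal colour and a darkened copy
      comp <- rbind(traj[k, ], traj[k, ] * 0.6)
      tex <- render_mosaic(length(a$rows), length(a$cols), comp, animal_patch_px)
      refl[a$rows, a$cols, ] <- tex
    }
    for (s in c("standard_low", "standard_high")) {
      r <- if (s == "standard_low") 0.086 else 0.958
      for (b in 1:3) refl[geom[[s]]$rows, geom[[s]]$cols, b] <- r
    }
    raw <- gain * refl + offset
    multiband_image(raw, bands, px_per_mm = 18, state = "raw")
  })
  names(images) <- as.character(times)
  masks <- trial_masks(geom, H, W)
  list(images = images, masks = masks,
       standards_reflectance = c(low = 0.086, high = 0.958),
       truth = list(individual = individual, treatment = treatment,
                    trial = as.integer(trial), times = times,
                    baseline = baseline_i, background = pal$bands,
                    lambda = config$approach_rate[[treatment]],
                    trajectory = traj, gain = gain, offset = offset))
}

trial_geometry <- function(H, W) {
  std <- 8L # standard patch edge
  a_h <- max(8L, floor(H * 0.4)); a_w <- max(8L, floor(W * 0.4))
  r0 <- floor((H - a_h) / 2); c0 <- floor((W - a_w) / 2)
  list(
    animal = list(rows = (r0 + 1):(r0 + a_h), cols = (c0 + 1):(c0 + a_w)),
    standard_low = list(rows = 2:(1 + std), cols = 2:(1 + std)),
    standard_high = list(rows = 2:(1 + std), cols = (W - std):(W - 1))
  )
}

trial_masks <- function(geom, H, W) {
  blank <- matrix(FALSE, H, W)
  mk <- function(region) {
    m <- blank
    m[region$rows, region$cols] <- TRUE
    m
  }
  animal <- mk(geom$animal)
  std_lo <- mk(geom$standard_low)
  std_hi <- mk(geom$standard_high)
  guard <- function(region, pad = 2L) {
    m <- blank
    rows <- max(1, min(region$rows) - pad):min(H, max(region$rows) + pad)
    cols <- max(1, min(region$cols) - pad):min(W, max(region$cols) + pad)
    m[rows, cols] <- TRUE
    m
  }
  background <- !(guard(geom$animal) | guard(geom$standard_low) |
                    guard(geom$standard_high))
  list(animal = roi_mask(animal), background = roi_mask(background),
       standard_low = roi_mask(std_lo), standard_high = roi_mask(std_hi))
}
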