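#' Pipeline configuration
#'
#' The file-based pipeline is driven by a single YAML configuration holding
#' the experiment block (see [experiment_config()]), the receptor set, and
#' the statistics options. `config_init()` writes a fully-populated default
#' configuration; `read_pipeline_config()` loads one back into the objects
#' the pipeline functions take.
#'
#' @param path YAML file path.
#' @param seed Seed recorded in the default config.
#' @return `config_init()` returns `path` invisibly; `read_pipeline_config()`
#'   a list with elements `experiment` ([experiment_config()]), `receptors`
#'   ([receptor_set()]) and `options`.
#' @export
config_init <- function(path, seed = 1) {
  cfg <- experiment_config(seed = seed)
  r <- receptor_set()
  yaml::write_yaml(list(
    experiment = list(
      n_individuals = cfg$n_individuals,
      treatments = as.list(cfg$treatments),
      time_points_min = lapply(cfg$time_points_min, as.list),
      approach_rate = as.list(cfg$approach_rate),
      individual_sd = cfg$individual_sd,
      noise_cv = cfg$noise_cv,
      seed = cfg$seed,
      img_height = cfg$img_height, img_width = cfg$img_width),
    receptors = list(
      names = as.list(r$names),
      relative_abundance = as.list(r$relative_abundance),
      weber_reference = r$weber_reference,
      achromatic_weber = r$achromatic_weber,
      achromatic = r$achromatic),
    options = list(measure_pattern = FALSE,
                   scale_series = list(min_scale = 2, multiplier = 1.414,
                                       max_scale = 724))
  ), path)
  invisible(path)
}

#' @rdname config_init
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort_chromatch(paste0("Config file not found: ", path),
                    "chromatch_validation_error")
  }
  raw <- yaml::read_yaml(path)
  exp <- raw$experiment
  experiment <- experiment_config(
    n_individuals = exp$n_individuals %||% 10,
    treatments = unlist(exp$treatments) %||% treatment_vocabulary(),
    time_points_min = lapply(exp$time_points_min, unlist),
    approach_rate = unlist(exp$approach_rate) %||% default_approach_rates(),
    individual_sd = exp$individual_sd %||% 0.10,
    noise_cv = exp$noise_cv %||% 0.05,
    seed = exp$seed,
    img_height = exp$img_height %||% 96, img_width = exp$img_width %||% 160)
  r <- raw$receptors
  receptors <- if (is.null(r)) receptor_set() else receptor_set(
    names = unlist(r$names),
    relative_abundance = unlist(r$relative_abundance),
    weber_reference = r$weber_reference %||% 0.05,
    achromatic_weber = r$achromatic_weber %||% 0.05,
    achromatic = r$achromatic %||% "dbl")
  list(experiment = experiment, receptors = receptors,
       options = raw$options %||% list())
}

#' Simulate an experiment to disk
#'
#' Renders every individual x treatment x trial of the configured synthetic
#' experiment as TIFF images plus PNG masks, writes the record-level table
#' and ground truth as CSV, and a `manifest.yml` enumerating every artifact
#' with its metadata. Fully deterministic given the config's seed.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_images Render and write the image series (set `FALSE` for a
#'   records-only simulation).
#' @param receptors,mapping Passed to [generate_records()].
#' @return Invisibly, the manifest as a list.
#' @export
cmd_simulate <- function(config, out_dir, write_images = TRUE,
                         receptors = receptor_set(),
                         mapping = default_catch_mapping()) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort_chromatch(paste0("Cannot create output directory: ", out_dir),
                    "chromatch_io_error")
  }
  gen <- generate_records(config, receptors, mapping)
  readr::write_csv(gen$records, file.path(out_dir, "records.csv"))
  readr::write_csv(gen$truth, file.path(out_dir, "truth.csv"))
  manifest <- list(seed = config$seed, records = "records.csv",
                   truth = "truth.csv", images = list())
  if (write_images) {
    img_dir <- file.path(out_dir, "images")
    mask_dir <- file.path(out_dir, "masks")
    dir.create(img_dir, showWarnings = FALSE)
    dir.create(mask_dir, showWarnings = FALSE)
    set.seed(config$seed + 1L) # rendering stream, distinct from the record stream
    mask_written <- FALSE
    for (tr in config$treatments) {
      for (i in seq_len(config$n_individuals)) {
        for (trial in names(trial_grids_for(config, tr))) {
          rt <- render_trial_images(config, tr, individual = i,
                                    trial = as.integer(trial))
          if (!mask_written) {
            for (m in names(rt$masks)) {
              write_mask(rt$masks[[m]], file.path(mask_dir, paste0(m, ".png")))
            }
            mask_written <- TRUE
          }
          for (t in names(rt$images)) {
            rel <- file.path("images",
                             sprintf("%s_ind%02d_trial%s_t%s.tif",
                                     tr, i, trial, t))
            write_multiband(rt$images[[t]], file.path(out_dir, rel))
            manifest$images[[length(manifest$images) + 1L]] <- list(
              path = rel, treatment = tr,
              individual_id = sprintf("ind%02d", i),
              trial = as.integer(trial), time_min = as.numeric(t))
          }
        }
      }
    }
    manifest$masks <- list(animal = "masks/animal.png",
                           background = "masks/background.png",
                           standard_low = "masks/standard_low.png",
                           standard_high = "masks/standard_high.png")
    manifest$standards <- list(reflectance_low = 0.086, reflectance_high = 0.958)
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}

#' Measure a simulated or photographed image set
#'
#' Walks the manifest written by [cmd_simulate()] (or an equivalent one for
#' real photographs), and for every image runs the measurement path:
#' linearize, normalize to reflectance against the grey standards measured
#' in-frame, extract ROI means, map to receptor catches, and compute the
#' chromatic and achromatic JNDs between animal and background. With
#' `measure_pattern = TRUE` the double-cone luminance image is additionally
#' decomposed into its pattern-energy spectrum for both ROIs and the pattern
#' metrics appended. Images that fail are logged and skipped, not fatal.
#'
#' @param in_dir Directory holding `manifest.yml`.
#' @param receptors A [receptor_set()].
#' @param mapping A [catch_mapping()].
#' @param measure_pattern Compute granularity metrics per image.
#' @param response Camera response spec for [linearize()].
#' @return A tibble of records (one per successfully measured image) with
#'   attribute `n_failed`; also written to `records_measured.csv` in
#'   `in_dir`.
#' @export
cmd_measure <- function(in_dir, receptors = receptor_set(),
                        mapping = default_catch_mapping(),
                        measure_pattern = FALSE,
                        response = response_identity()) {
  manifest_path <- file.path(in_dir, "manifest.yml")
  if (!file.exists(manifest_path)) {
    abort_chromatch(paste0("No manifest.yml in ", in_dir),
                    "chromatch_validation_error")
  }
  manifest <- yaml::read_yaml(manifest_path)
  if (length(manifest$images) == 0L) {
    abort_chromatch("Manifest lists no images.", "chromatch_validation_error")
  }
  masks <- lapply(manifest$masks, function(p) read_mask(file.path(in_dir, p)))
  failures <- character()
  rows <- purrr::map(manifest$images, function(entry) {
    tryCatch({
      img <- read_multiband(file.path(in_dir, entry$path))
      lin <- linearize(img, response)
      std <- grey_standard_pair(
        measured_low = extract_roi_mean(lin, masks$standard_low),
        measured_high = extract_roi_mean(lin, masks$standard_high),
        reflectance_low = manifest$standards$reflectance_low,
        reflectance_high = manifest$standards$reflectance_high)
      refl <- normalize_to_reflectance(lin, std)
      q_animal <- catches_from_bands(extract_roi_mean(refl, masks$animal), mapping)
      q_bg <- catches_from_bands(extract_roi_mean(refl, masks$background), mapping)
      jnd <- compare_rois(q_animal, q_bg, receptors)
      rec <- tibble::tibble(
        individual_id = entry$individual_id, trial = entry$trial,
        treatment = entry$treatment, time_min = entry$time_min,
        chromatic_jnd = jnd$chromatic_jnd,
        achromatic_jnd = jnd$achromatic_jnd,
        luminance = q_animal[[receptors$achromatic]])
      if (measure_pattern) {
        lum <- luminance_image(refl, mapping, receptors$achromatic)
        series <- build_scale_series(max_scale = min(dim(lum)))
        spec_a <- energy_spectrum(lum, masks$animal, series)
        spec_b <- energy_spectrum(lum, masks$background, series)
        rec <- dplyr::bind_cols(rec, pattern_metrics(spec_a, spec_b))
      }
      rec
    }, error = function(e) {
      failures <<- c(failures, paste0(entry$path, ": ", conditionMessage(e)))
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  if (length(failures)) {
    message(sprintf("%d image(s) failed measurement:\n%s",
                    length(failures), paste(" -", failures, collapse = "\n")))
  }
  if (nrow(out)) readr::write_csv(out, file.path(in_dir, "records_measured.csv"))
  attr(out, "n_failed") <- length(failures)
  out
}

#' Analyse a record table
#'
#' Runs the trend-model stage on a measured or simulated record table:
#' splits the treatments present into the hue family (uniform colours,
#' response = chromatic JND, individual and trial random intercepts) and the
#' greyscale family (grey/black/white, response = double-cone luminance,
#' individual random intercept), fits the time-by-treatment model per
#' family, and emits per-treatment slope tables, BH-adjusted pairwise slope
#' contrasts, and the interaction likelihood-ratio test.
#'
#' @param records A record tibble (from [cmd_measure()] or
#'   [generate_records()]) or a CSV path.
#' @param out_dir Optional directory for `slopes_*.csv`, `contrasts_*.csv`
#'   and `report.txt`.
#' @return A named list per analysed family, each with `fit`, `slopes`,
#'   `contrasts`, `interaction`.
#' @export
cmd_analyse <- function(records, out_dir = NULL) {
  if (is.character(records)) {
    if (!file.exists(records)) {
      abort_chromatch(paste0("Records file not found: ", records),
                      "chromatch_validation_error")
    }
    records <- readr::read_csv(records, show_col_types = FALSE)
  }
  records <- tibble::as_tibble(records)
  needed <- c("individual_id", "trial", "treatment", "time_min")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort_chromatch(paste0("Records are missing columns: ",
                           paste(missing, collapse = ", ")),
                    "chromatch_validation_error")
  }
  fams <- list(
    colour = list(treatments = c("yellow", "yellow-green", "orange", "blue-green"),
                  response = "chromatic_jnd",
                  random_terms = c("individual", "trial")),
    greyscale = list(treatments = c("grey", "black", "white"),
                     response = "luminance",
                     random_terms = "individual"),
    pattern = list(treatments = grep("-(small|medium|large)$",
                                     treatment_vocabulary(), value = TRUE),
                   response = "energy_diff_at_dominant",
                   random_terms = "individual")
  )
  results <- list()
  for (fam in names(fams)) {
    spec <- fams[[fam]]
    sub <- dplyr::filter(records, .data$treatment %in% spec$treatments)
    if (length(unique(sub$treatment)) < 2L || !spec$response %in% names(sub) ||
        all(is.na(sub[[spec$response]]))) next
    fit <- fit_time_by_treatment(sub, !!spec$response,
                                 random_terms = spec$random_terms)
    results[[fam]] <- list(
      fit = fit,
      slopes = slope_table(fit),
      contrasts = pairwise_slope_contrasts(fit),
      interaction = interaction_test(fit))
  }
  if (length(results) == 0L) {
    abort_chromatch("No analysable treatment family (need >= 2 treatments with a response).",
                    "chromatch_design_error")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (fam in names(results)) {
      readr::write_csv(results[[fam]]$slopes,
                       file.path(out_dir, paste0("slopes_", fam, ".csv")))
      readr::write_csv(results[[fam]]$contrasts,
                       file.path(out_dir, paste0("contrasts_", fam, ".csv")))
    }
    writeLines(analysis_report(results), file.path(out_dir, "report.txt"))
  }
  results
}

analysis_report <- function(results) {
  out <- c("chromatch trend analysis", strrep("=", 24), "")
  for (fam in names(results)) {
    res <- results[[fam]]
    out <- c(out, sprintf("[%s] response: %s", fam, res$fit$response),
             sprintf("  interaction LRT: chisq = %.3f, df = %d, p = %.4g",
                     res$interaction$chisq, res$interaction$df,
                     res$interaction$p_value),
             "  slopes (per minute):")
    for (k in seq_len(nrow(res$slopes))) {
      s <- res$slopes[k, ]
      out <- c(out, sprintf("    %-22s %+.4f (se %.4f, t = %+.3f, p = %.4g)",
                            s$treatment, s$slope, s$se, s$t_ratio, s$p_value))
    }
    out <- c(out, "")
  }
  out
}
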