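test_that("the background palette covers the treatment vocabulary", {
  expect_length(treatment_vocabulary(), 13)
  for (tr in treatment_vocabulary()) {
    pal <- background_palette(tr)
    expect_true(all(pal$bands > 0)) # catches stay strictly positive
  }
  expect_error(background_palette("mauve"), class = "chromatch_vocabulary_error")
})

test_that("greyscale treatments share chromatic ratios, differ in brightness", {
  g <- background_palette("grey")$bands
  w <- background_palette("white")$bands
  b <- background_palette("black")$bands
  expect_equal(g / g[["sw"]], w / w[["sw"]], tolerance = 1e-12)
  expect_equal(g / g[["sw"]], b / b[["sw"]], tolerance = 1e-12)
  expect_true(b[["mw"]] < g[["mw"]] && g[["mw"]] < w[["mw"]])
  # zero chromatic JND between greyscale pairs, nonzero achromatic
  r <- receptor_set(); m <- default_catch_mapping()
  res <- compare_rois(catches_from_bands(g, m), catches_from_bands(w, m), r)
  expect_equal(res$chromatic_jnd, 0, tolerance = 1e-10)
  expect_gt(res$achromatic_jnd, 1)
})

test_that("patterned treatments share components across three patch sizes", {
  sizes <- sapply(c("small", "medium", "large"), function(s) {
    background_palette(paste0("black-white-", s))$patch_px
  })
  expect_length(unique(sizes), 3)
  expect_true(all(diff(sizes) > 0))
  comps <- lapply(c("small", "medium", "large"), function(s) {
    background_palette(paste0("green-yellow-", s))$components
  })
  expect_identical(comps[[1]], comps[[2]])
  expect_identical(comps[[2]], comps[[3]])
})

test_that("trajectories decay exponentially toward the background", {
  expect_equal(unname(simulate_trajectory(1, 2, lambda = 0.1, times = 10)[1, 1]),
               2 - exp(-1), tolerance = 1e-12)
  flat <- simulate_trajectory(c(a = 1, b = 2), c(a = 3, b = 4), lambda = 0,
                              times = c(0, 5, 10))
  expect_equal(unname(flat), matrix(c(1, 1, 1, 2, 2, 2), 3), tolerance = 1e-12)
  fast <- simulate_trajectory(1, 2, lambda = 50, times = c(0, 1, 5))
  expect_equal(unname(fast[2:3, 1]), c(2, 2), tolerance = 1e-6)
  expect_equal(unname(fast[1, 1]), 1)
})

test_that("trajectory noise is multiplicative, mean-one, and seed-stable", {
  set.seed(200)
  a <- simulate_trajectory(rep(1, 3), rep(1, 3), 0, times = 1:500, noise_cv = 0.2)
  expect_equal(mean(a), 1, tolerance = 0.03)
  expect_equal(sd(a) / mean(a), 0.2, tolerance = 0.03)
  set.seed(201)
  b1 <- simulate_trajectory(1, 2, 0.1, times = 0:5, noise_cv = 0.1)
  set.seed(201)
  b2 <- simulate_trajectory(1, 2, 0.1, times = 0:5, noise_cv = 0.1)
  expect_identical(b1, b2)
})

test_that("generate_records is deterministic given the seed", {
  cfg <- experiment_config(n_individuals = 3,
                           treatments = c("yellow", "grey"), seed = 77)
  g1 <- generate_records(cfg)
  g2 <- generate_records(cfg)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_records(experiment_config(n_individuals = 3,
                                           treatments = c("yellow", "grey"),
                                           seed = 78))
  expect_false(identical(g1$records, g3$records))
})

test_that("records carry the experiment's design structure", {
  cfg <- experiment_config(n_individuals = 4,
                           treatments = c("yellow", "black", "black-white-small"),
                           seed = 300)
  recs <- generate_records(cfg)$records
  # colour treatments get both trials, others only the first
  expect_identical(sort(unique(recs$trial[recs$treatment == "yellow"])), 1:2)
  expect_identical(unique(recs$trial[recs$treatment == "black"]), 1L)
  n_yellow <- 4 * (9 + 5)
  expect_identical(sum(recs$treatment == "yellow"), as.integer(n_yellow))
  expect_true(all(recs$time_min >= 0 & recs$time_min <= 21))
  expect_true(all(recs$chromatic_jnd >= 0))
  expect_true(all(recs$luminance > 0))
})

test_that("a positive approach rate shrinks the expected JND over time", {
  cfg <- experiment_config(n_individuals = 8, treatments = "yellow",
                           approach_rate = c(yellow = 0.15),
                           noise_cv = 0.05, seed = 301)
  recs <- generate_records(cfg)$records
  mean_by_time <- tapply(recs$chromatic_jnd, recs$time_min, mean)
  times <- as.numeric(names(mean_by_time))
  expect_lt(mean_by_time[[length(times)]], mean_by_time[[1]] / 2)
  expect_lt(stats::cor(times, mean_by_time), -0.8)
})

test_that("a zero approach rate yields slopes centred on zero", {
  slopes <- sapply(1:20, function(k) {
    cfg <- experiment_config(n_individuals = 6, treatments = c("grey", "white"),
                             approach_rate = c(grey = 0, white = 0),
                             seed = 400 + k)
    recs <- generate_records(cfg)$records
    fit <- suppressWarnings(suppressMessages(
      fit_time_by_treatment(recs, luminance, random_terms = "individual")))
    slope_table(fit)$slope
  })
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(length(slopes)) + 1e-4)
})

test_that("rendered grey standards recover their reflectances through calibration", {
  cfg <- experiment_config(n_individuals = 1, treatments = "yellow",
                           noise_cv = 0, individual_sd = 0, seed = 500)
  set.seed(500)
  rt <- render_trial_images(cfg, "yellow")
  img <- rt$images[[1]]
  expect_identical(img$state, "raw")
  lin <- linearize(img)
  std <- grey_standard_pair(
    measured_low = extract_roi_mean(lin, rt$masks$standard_low),
    measured_high = extract_roi_mean(lin, rt$masks$standard_high))
  refl <- normalize_to_reflectance(lin, std)
  expect_equal(unname(extract_roi_mean(refl, rt$masks$standard_low)),
               rep(0.086, 3), tolerance = 1e-10)
  expect_equal(unname(extract_roi_mean(refl, rt$masks$standard_high)),
               rep(0.958, 3), tolerance = 1e-10)
})

test_that("with fast approach the rendered animal converges to the background", {
  cfg <- experiment_config(n_individuals = 1, treatments = "orange",
                           approach_rate = c(orange = 5), noise_cv = 0,
                           individual_sd = 0, seed = 501)
  set.seed(501)
  rt <- render_trial_images(cfg, "orange")
  last <- rt$images[[length(rt$images)]]
  lin <- linearize(last)
  std <- grey_standard_pair(
    measured_low = extract_roi_mean(lin, rt$masks$standard_low),
    measured_high = extract_roi_mean(lin, rt$masks$standard_high))
  refl <- normalize_to_reflectance(lin, std)
  expect_equal(extract_roi_mean(refl, rt$masks$animal),
               extract_roi_mean(refl, rt$masks$background), tolerance = 1e-3)
})

test_that("mosaic dominant scales are ordered in patch size and oracle-consistent", {
  set.seed(502)
  comp <- rbind(c(0.05, 0.05, 0.05), c(0.9, 0.9, 0.9))
  doms <- sapply(c(8, 16, 32), function(patch) {
    mos <- render_mosaic(192, 192, comp, patch)
    dominant_scale(energy_spectrum(mos[, , 1], full_mask(192),
                                   build_scale_series(max_scale = 192)))
  })
  expect_true(all(diff(doms) > 0))
  # the random block process concentrates energy above the patch edge
  expect_true(all(doms >= c(8, 16, 32)))
  expect_true(all(doms <= 4 * c(8, 16, 32)))
  expect_error(render_mosaic(32, 32, comp, 64),
               class = "chromatch_configuration_error")
})

test_that("record-level and image-level paths agree in noiseless conditions", {
  cfg <- experiment_config(n_individuals = 1, treatments = "yellow",
                           noise_cv = 0, individual_sd = 0, seed = 503)
  gen <- generate_records(cfg)
  sub <- gen$records[gen$records$trial == 1, ]
  set.seed(503)
  rt <- render_trial_images(cfg, "yellow", trial = 1)
  r <- receptor_set(); mp <- default_catch_mapping()
  for (k in seq_along(rt$images)) {
    lin <- linearize(rt$images[[k]])
    std <- grey_standard_pair(
      measured_low = extract_roi_mean(lin, rt$masks$standard_low),
      measured_high = extract_roi_mean(lin, rt$masks$standard_high))
    refl <- normalize_to_reflectance(lin, std)
    qa <- catches_from_bands(extract_roi_mean(refl, rt$masks$animal), mp)
    qb <- catches_from_bands(extract_roi_mean(refl, rt$masks$background), mp)
    jnd <- compare_rois(qa, qb, r)
    expect_equal(jnd$chromatic_jnd, sub$chromatic_jnd[k], tolerance = 1e-3)
    expect_equal(qa[["dbl"]], sub$luminance[k], tolerance = 1e-3)
  }
})

test_that("experiment configuration is validated", {
  expect_error(experiment_config(), class = "chromatch_validation_error")
  expect_error(experiment_config(seed = 1, treatments = "puce"),
               class = "chromatch_vocabulary_error")
  expect_error(experiment_config(seed = 1, noise_cv = -0.1),
               class = "chromatch_validation_error")
  expect_error(experiment_config(seed = 1,
                                 time_points_min = list(trial1 = c(3, 1),
                                                        trial2 = c(0, 1))),
               class = "chromatch_validation_error")
})
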