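quiet_fit <- function(...) {
  suppressWarnings(suppressMessages(fit_time_by_treatment(...)))
}

test_that("noiseless linear data is recovered exactly", {
  recs <- simulate_trend_records(slopes = c(a = -0.05, b = 0),
                                 n_individuals = 4, individual_sd = 0,
                                 sigma = 0, seed = 101)
  fit <- quiet_fit(recs, response, random_terms = "individual")
  st <- slope_table(fit)
  expect_equal(st$slope[st$treatment == "a"], -0.05, tolerance = 1e-6)
  expect_equal(st$slope[st$treatment == "b"], 0, tolerance = 1e-6)
})

test_that("tidy() returns the slope table and glance() the fit summary", {
  recs <- simulate_trend_records(slopes = c(a = -0.05, b = 0.02),
                                 n_individuals = 5, seed = 102)
  fit <- quiet_fit(recs, "response", random_terms = "individual")
  expect_identical(tidy(fit), slope_table(fit))
  g <- glance(fit)
  expect_identical(g$nobs, nrow(recs))
  expect_true(g$REML)
  expect_named(tidy(fit), c("treatment", "slope", "se", "df", "lower_cl",
                            "upper_cl", "t_ratio", "p_value"))
  expect_true(all(tidy(fit)$lower_cl < tidy(fit)$slope &
                    tidy(fit)$slope < tidy(fit)$upper_cl))
})

test_that("slope table agrees with emmeans trend estimates", {
  recs <- simulate_trend_records(slopes = c(a = -0.06, b = 0, c = 0.03),
                                 n_individuals = 6, trial_sd = 0.3, seed = 103)
  fit <- quiet_fit(recs, response)
  st <- slope_table(fit)
  em <- as.data.frame(emmeans::emtrends(fit$fit, ~treatment, var = "time_min",
                                        lmer.df = "satterthwaite"))
  em <- em[match(st$treatment, as.character(em$treatment)), ]
  expect_equal(st$slope, em$time_min.trend, tolerance = 1e-8)
  expect_equal(st$se, em$SE, tolerance = 1e-8)
  expect_equal(st$df, em$df, tolerance = 1e-4)
  expect_equal(st$lower_cl, em$lower.CL, tolerance = 1e-6)
  expect_equal(st$upper_cl, em$upper.CL, tolerance = 1e-6)
})

test_that("pairwise contrasts equal slope differences and are BH adjusted", {
  recs <- simulate_trend_records(slopes = c(a = -0.06, b = 0, c = 0.03),
                                 n_individuals = 6, seed = 104)
  fit <- quiet_fit(recs, response, random_terms = "individual")
  st <- slope_table(fit)
  ct <- pairwise_slope_contrasts(fit)
  expect_identical(nrow(ct), 3L) # choose(3, 2)
  ab <- ct$estimate[ct$contrast == "a versus b"]
  expect_equal(ab, st$slope[st$treatment == "a"] - st$slope[st$treatment == "b"],
               tolerance = 1e-10)
  expect_equal(ct$p_adjusted, bh_adjust(ct$p_value))
  expect_true(all(ct$p_adjusted >= ct$p_value))
})

test_that("noiseless equal slopes give a zero contrast", {
  recs <- simulate_trend_records(slopes = c(a = -0.02, b = -0.02),
                                 n_individuals = 4, individual_sd = 0.5,
                                 sigma = 0, seed = 105)
  fit <- quiet_fit(recs, response, random_terms = "individual")
  ct <- pairwise_slope_contrasts(fit)
  expect_equal(ct$estimate, 0, tolerance = 1e-8)
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.5, 0.9)),
               c(0.06, 0.06, 0.06, 0.06, 0.6, 0.9))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(106)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    # identical rejection sets at a grid of thresholds
    for (alpha in c(0.01, 0.05, 0.1)) {
      expect_identical(adj <= alpha, bh_oracle(p) <= alpha)
    }
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "chromatch_domain_error")
  expect_error(bh_adjust(c(-0.1)), class = "chromatch_domain_error")
})

test_that("the interaction LRT is zero on self-comparison and positive under effect", {
  recs <- simulate_trend_records(slopes = c(a = -0.06, b = 0.06),
                                 n_individuals = 6, seed = 107)
  fit <- quiet_fit(recs, response, random_terms = "individual")
  self <- interaction_test(fit, fit)
  expect_equal(self$chisq, 0, tolerance = 1e-8)
  expect_identical(self$df, 0L)

  it <- interaction_test(fit)
  expect_identical(it$df, 1L) # 2 treatments -> one interaction parameter
  expect_gt(it$chisq, 0)
  expect_lt(it$p_value, 0.01) # strong interaction built in
  expect_equal(it$chisq, 2 * (it$logLik_full - it$logLik_reduced),
               tolerance = 1e-10)
})

test_that("the LRT statistic grows with the interaction effect size", {
  stats <- sapply(c(0, 0.02, 0.06), function(delta) {
    recs <- simulate_trend_records(slopes = c(a = 0, b = delta),
                                   n_individuals = 8, sigma = 0.3, seed = 108)
    suppressMessages(interaction_test(quiet_fit(recs, response,
                                                random_terms = "individual"))$chisq)
  })
  expect_true(all(diff(stats) > 0))
})

test_that("design validation rejects degenerate inputs", {
  recs <- simulate_trend_records(slopes = c(a = -0.05), n_individuals = 4,
                                 seed = 109)
  expect_error(fit_time_by_treatment(recs, response, "individual"),
               class = "chromatch_design_error")
  one_time <- simulate_trend_records(slopes = c(a = 0, b = 0),
                                     n_individuals = 4,
                                     time_points_min = list(trial1 = c(0, 5)),
                                     seed = 110)
  one_time <- one_time[one_time$time_min == 0, ]
  expect_error(fit_time_by_treatment(one_time, response, "individual"),
               class = "chromatch_design_error")
  two <- simulate_trend_records(slopes = c(a = 0, b = 0), n_individuals = 1,
                                seed = 111)
  expect_error(fit_time_by_treatment(two, response, "individual"),
               class = "chromatch_design_error")
  expect_error(fit_time_by_treatment(dplyr::rename(recs, y = response), response),
               class = "chromatch_validation_error")
})

test_that("the pattern-matching ANOVA matches a hand-computed F", {
  set.seed(112)
  x <- c(rnorm(36, 10, 1), rnorm(36, 20, 1))
  g <- rep(c(FALSE, TRUE), each = 36)
  res <- pdd_matching_anova(tibble::tibble(pdd = x, exposed = g))
  expect_equal(res$f_statistic, anova_f_oracle(x, g), tolerance = 1e-10)
  expect_gt(res$f_statistic, 100)
  expect_lt(res$p_value, 1e-6)
  expect_identical(res$df_between, 1L)
  expect_identical(res$df_within, 70L)

  # identical groups -> F near zero
  same <- tibble::tibble(pdd = rep(c(1, 2, 3), 4),
                         exposed = rep(c(TRUE, FALSE), each = 6))
  expect_lt(pdd_matching_anova(same)$f_statistic, 1e-20)

  expect_error(pdd_matching_anova(tibble::tibble(pdd = 1:5, exposed = TRUE)),
               class = "chromatch_design_error")
})

test_that("the matching ANOVA p-value is uniform under the null", {
  set.seed(113)
  ps <- replicate(400, {
    d <- tibble::tibble(pdd = rnorm(40), exposed = rep(c(TRUE, FALSE), 20))
    pdd_matching_anova(d)$p_value
  })
  # Kolmogorov-Smirnov against U(0,1)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("permuted time labels do not produce spurious trends", {
  set.seed(114)
  recs <- simulate_trend_records(slopes = c(a = -0.05, b = 0.02),
                                 n_individuals = 6, sigma = 0.5, seed = 115)
  tstats <- replicate(30, {
    perm <- recs |>
      dplyr::group_by(individual_id, treatment) |>
      dplyr::mutate(time_min = sample(time_min)) |>
      dplyr::ungroup()
    st <- slope_table(quiet_fit(perm, response, random_terms = "individual"))
    st$t_ratio
  })
  # null t-ratios centred on zero with roughly unit spread
  expect_lt(abs(mean(tstats)), 0.5)
  expect_gt(mean(abs(tstats) < 2.5), 0.9)
})
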