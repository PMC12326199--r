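#' Fit the time-by-treatment mixed model
#'
#' The workhorse of the trend analysis: a linear mixed-effects model of a
#' matching response (chromatic JND, double-cone luminance, or a pattern
#' metric) with fixed effects for time, treatment and their interaction, and
#' random intercepts for individual and (optionally) trial:
#' `response ~ time_min * treatment + (1 | individual_id) [+ (1 | trial)]`.
#' Time is continuous, in minutes. Fits use REML; use [interaction_test()]
#' for the ML likelihood-ratio comparison of nested fixed structures.
#'
#' @param records A data frame of per-photograph records with columns
#'   `individual_id`, `treatment`, `time_min`, the response, and `trial` when
#'   used as a random term.
#' @param response Response column, as a bare name or string.
#' @param random_terms Character subset of `c("individual", "trial")`.
#' @return A `trend_fit` object wrapping the `lmerTest` fit; use [tidy()] or
#'   [slope_table()] for per-treatment trends and
#'   [pairwise_slope_contrasts()] for treatment comparisons.
#' @export
#' @examples
#' recs <- simulate_trend_records(slopes = c(a = -0.05, b = 0), seed = 1)
#' fit <- fit_time_by_treatment(recs, response)
#' tidy(fit)
fit_time_by_treatment <- function(records, response,
                                  random_terms = c("individual", "trial")) {
  records <- tibble::as_tibble(records)
  resp <- resolve_column(rlang::enquo(response), records)
  random_terms <- match.arg(random_terms, c("individual", "trial"),
                            several.ok = TRUE)
  needed <- c("individual_id", "treatment", "time_min", resp,
              if ("trial" %in% random_terms) "trial")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort_chromatch(paste0("Missing record columns: ", paste(missing, collapse = ", ")),
                    "chromatch_validation_error")
  }
  records$treatment <- factor(records$treatment)
  records$individual_id <- factor(records$individual_id)
  if (nlevels(records$treatment) < 2L) {
    abort_chromatch("At least two treatments are required to fit the interaction model.",
                    "chromatch_design_error")
  }
  n_times <- tapply(records$time_min, records$treatment,
                    function(x) length(unique(x)))
  if (any(n_times < 2L)) {
    abort_chromatch("Every treatment needs at least two time points.",
                    "chromatch_design_error")
  }
  if (nlevels(records$individual_id) < 2L) {
    abort_chromatch("At least two individuals are required for the random intercept.",
                    "chromatch_design_error")
  }
  re <- c(if ("individual" %in% random_terms) "(1 | individual_id)",
          if ("trial" %in% random_terms) "(1 | trial)")
  if (is.null(re)) {
    abort_chromatch("At least one random term is required.", "chromatch_design_error")
  }
  if ("trial" %in% random_terms) records$trial <- factor(records$trial)
  form <- as.formula(paste0(resp, " ~ time_min * treatment + ",
                            paste(re, collapse = " + ")))
  fit <- tryCatch(
    lmerTest::lmer(form, data = records, REML = TRUE),
    error = function(e) {
      abort_chromatch(paste0("Mixed-model fit failed: ", conditionMessage(e)),
                      "chromatch_fit_error", parent = e)
    })
  structure(
    list(fit = fit, response = resp, formula = form,
         random_terms = random_terms, data = records,
         treatments = levels(records$treatment)),
    class = "trend_fit"
  )
}

resolve_column <- function(quo, data) {
  expr <- rlang::quo_get_expr(quo)
  if (is.character(expr)) return(expr)
  rlang::as_name(quo)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s over time x treatment (%d treatments, %d rows)\n",
              x$response, length(x$treatments), nrow(x$data)))
  cat("  formula:", deparse(x$formula), "\n")
  invisible(x)
}

# Fixed-effect design row for a given treatment/time, on the fit's terms.
fixed_design_row <- function(object, treatment, time_min) {
  form <- lme4::nobars(formula(object$fit))
  tt <- delete.response(terms(form))
  nd <- data.frame(time_min = time_min,
                   treatment = factor(treatment, levels = object$treatments))
  model.matrix(tt, nd)
}

slope_contrast_vector <- function(object, treatment) {
  x1 <- fixed_design_row(object, treatment, 1)
  x0 <- fixed_design_row(object, treatment, 0)
  drop(x1 - x0)
}

contrast_inference <- function(object, L) {
  res <- tryCatch(
    lmerTest::contest1D(object$fit, L, confint = TRUE),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$df)) {
    # Satterthwaite unavailable: fall back to residual df
    beta <- lme4::fixef(object$fit)
    V <- as.matrix(stats::vcov(object$fit))
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    df <- nrow(object$data) - length(beta)
    tv <- est / se
    res <- data.frame(Estimate = est, `Std. Error` = se, df = df,
                      `t value` = tv,
                      lower = est - qt(0.975, df) * se,
                      upper = est + qt(0.975, df) * se,
                      `Pr(>|t|)` = 2 * stats::pt(-abs(tv), df),
                      check.names = FALSE)
  }
  tibble::tibble(
    estimate = res$Estimate, se = res$`Std. Error`, df = res$df,
    lower_cl = res$lower, upper_cl = res$upper,
    t_ratio = res$`t value`, p_value = res$`Pr(>|t|)`
  )
}

#' Per-treatment time trends
#'
#' Marginal slope of the response over time for each treatment, with
#' standard errors, Satterthwaite degrees of freedom, 95% confidence limits,
#' t-ratios and p-values. For matching responses (JND to the background) a
#' negative slope means the animal grows more similar to its background over
#' time.
#'
#' @param object A [fit_time_by_treatment()] fit.
#' @return A tibble with one row per treatment: `treatment`, `slope`, `se`,
#'   `df`, `lower_cl`, `upper_cl`, `t_ratio`, `p_value`.
#' @export
slope_table <- function(object) {
  stopifnot(inherits(object, "trend_fit"))
  purrr::map_dfr(object$treatments, function(tr) {
    out <- contrast_inference(object, slope_contrast_vector(object, tr))
    dplyr::bind_cols(tibble::tibble(treatment = tr),
                     dplyr::rename(out, slope = "estimate"))
  })
}

#' @rdname slope_table
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) slope_table(x)

#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  ll <- logLik(x$fit)
  tibble::tibble(
    nobs = stats::nobs(x$fit),
    n_treatments = length(x$treatments),
    sigma = stats::sigma(x$fit),
    logLik = as.numeric(ll),
    df = attr(ll, "df"),
    REML = lme4::isREML(x$fit)
  )
}

#' Pairwise slope contrasts with Benjamini-Hochberg correction
#'
#' Differences between every pair of per-treatment time slopes, each tested
#' against zero, with p-values adjusted across the family of pairs by the
#' Benjamini-Hochberg step-up rule. A significant contrast means the two
#' backgrounds elicit different rates of change.
#'
#' @param object A [fit_time_by_treatment()] fit.
#' @return A tibble with one row per treatment pair: `contrast`, `estimate`,
#'   `se`, `df`, `t_ratio`, `p_value`, `p_adjusted`.
#' @export
pairwise_slope_contrasts <- function(object) {
  stopifnot(inherits(object, "trend_fit"))
  trts <- object$treatments
  pairs <- utils::combn(trts, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    L <- slope_contrast_vector(object, pr[1]) - slope_contrast_vector(object, pr[2])
    res <- contrast_inference(object, L)
    dplyr::bind_cols(
      tibble::tibble(contrast = paste(pr[1], "versus", pr[2])),
      dplyr::select(res, -"lower_cl", -"upper_cl"))
  })
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment of a family of p-values. Thin validated
#' wrapper over `stats::p.adjust(method = "BH")`; adjusted values never fall
#' below the raw ones and are capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    abort_chromatch("p-values must lie in [0, 1].", "chromatch_domain_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Likelihood-ratio test for the time-by-treatment interaction
#'
#' Compares the full model against the nested model without the interaction
#' term by a likelihood-ratio chi-square. Both models are refitted with
#' maximum likelihood (REML log-likelihoods are not comparable across fixed
#' structures); degrees of freedom equal the fixed-parameter difference.
#'
#' @param full A [fit_time_by_treatment()] fit.
#' @param reduced Optional nested `trend_fit`; by default the full model is
#'   refitted without the `time_min:treatment` interaction.
#' @return A tibble with `chisq`, `df`, `p_value`, `logLik_full`,
#'   `logLik_reduced`.
#' @export
interaction_test <- function(full, reduced = NULL) {
  stopifnot(inherits(full, "trend_fit"))
  ml_full <- refit_ml(full$fit)
  ml_reduced <- if (is.null(reduced)) {
    re <- c(if ("individual" %in% full$random_terms) "(1 | individual_id)",
            if ("trial" %in% full$random_terms) "(1 | trial)")
    form <- as.formula(paste0(full$response, " ~ time_min + treatment + ",
                              paste(re, collapse = " + ")))
    lmerTest::lmer(form, data = full$data, REML = FALSE)
  } else {
    stopifnot(inherits(reduced, "trend_fit"))
    if (stats::nobs(reduced$fit) != stats::nobs(full$fit)) {
      abort_chromatch("Models were fitted to different data; not nested.",
                      "chromatch_nesting_error")
    }
    refit_ml(reduced$fit)
  }
  df_full <- length(lme4::fixef(ml_full))
  df_reduced <- length(lme4::fixef(ml_reduced))
  if (df_reduced > df_full) {
    abort_chromatch("`reduced` has more fixed parameters than `full`; not nested.",
                    "chromatch_nesting_error")
  }
  ll_f <- as.numeric(logLik(ml_full))
  ll_r <- as.numeric(logLik(ml_reduced))
  stat <- max(0, 2 * (ll_f - ll_r))
  df <- df_full - df_reduced
  tibble::tibble(
    chisq = stat, df = df,
    p_value = if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_,
    logLik_full = ll_f, logLik_reduced = ll_r
  )
}

refit_ml <- function(fit) {
  if (lme4::isREML(fit)) lme4::refitML(fit) else fit
}

#' Pattern-matching ANOVA on pattern distribution differences
#'
#' Tests whether animals' patterning matches the spatial frequency they were
#' exposed to more closely than the other candidate frequencies: a one-way
#' ANOVA of pattern distribution difference by an exposed / non-exposed
#' label, run within one colour family at a time (e.g. black/white, or
#' green/yellow).
#'
#' @param data A data frame with one PDD value per animal x compared scale.
#' @param pdd Column of pattern distribution differences (bare name or
#'   string).
#' @param exposed Column labelling whether the compared scale is the one the
#'   animal was exposed to (logical or two-level factor).
#' @return A tibble with `f_statistic`, `df_between`, `df_within`, `p_value`,
#'   and the group means.
#' @export
pdd_matching_anova <- function(data, pdd = "pdd", exposed = "exposed") {
  data <- tibble::as_tibble(data)
  pdd_col <- resolve_column(rlang::enquo(pdd), data)
  exp_col <- resolve_column(rlang::enquo(exposed), data)
  missing <- setdiff(c(pdd_col, exp_col), names(data))
  if (length(missing)) {
    abort_chromatch(paste0("Missing columns: ", paste(missing, collapse = ", ")),
                    "chromatch_validation_error")
  }
  g <- factor(data[[exp_col]])
  if (nlevels(g) < 2L) {
    abort_chromatch("Fewer than two groups (exposed / non-exposed) present.",
                    "chromatch_design_error")
  }
  fit <- aov(data[[pdd_col]] ~ g)
  tab <- anova(fit)
  means <- tapply(data[[pdd_col]], g, mean)
  exposed_level <- if ("TRUE" %in% levels(g)) "TRUE" else levels(g)[nlevels(g)]
  tibble::tibble(
    f_statistic = tab$`F value`[1],
    df_between = tab$Df[1], df_within = tab$Df[2],
    p_value = tab$`Pr(>F)`[1],
    mean_exposed = unname(means[exposed_level]),
    mean_other = mean(data[[pdd_col]][g != exposed_level])
  )
}
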