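#' Two-sample Student t-test from vectors or summaries
#'
#' Pooled-variance two-tailed Student t-test (Welch behind a flag). Accepts
#' either two raw vectors or the group summaries `(n, mean, sd)`; the
#' statistic is oriented as `mean2 - mean1`, so passing the ASD group first
#' and the TD group second reports TD minus ASD.
#'
#' @param x,y Raw vectors (alternative to the summary interface).
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summaries.
#' @param welch Use the Welch unequal-variance statistic instead.
#'
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x = NULL, y = NULL,
                         n1 = NULL, mean1 = NULL, sd1 = NULL,
                         n2 = NULL, mean2 = NULL, sd2 = NULL,
                         welch = FALSE) {
  if (!is.null(x)) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    n1 <- length(x); mean1 <- mean(x); sd1 <- stats::sd(x)
    n2 <- length(y); mean2 <- mean(y); sd2 <- stats::sd(y)
  }
  if (n1 < 2 || n2 < 2) {
    stop_alphapaf("both groups need n >= 2", "alphapaf_config_error")
  }
  if (sd1 < 0 || sd2 < 0) {
    stop_alphapaf("standard deviations must be >= 0", "alphapaf_config_error")
  }
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  diff <- mean2 - mean1
  t <- if (se == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else diff / se
  list(t = t, df = df, p = if (is.finite(t)) 2 * stats::pt(-abs(t), df) else 0)
}

#' Pearson chi-square test for a 2x2 table
#'
#' @param a,b,c,d Cell counts, row-wise: `(a, b)` over `(c, d)`.
#' @param correct Apply the Yates continuity correction.
#'
#' @return List with `statistic`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_alphapaf("cell counts must be non-negative integers",
                  "alphapaf_config_error")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_alphapaf("table has a zero margin", "alphapaf_config_error")
  }
  ct <- stats::chisq.test(m, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Pearson chi-square test for an r x c table
#'
#' @param table Matrix of non-negative counts, at least 2x2.
#'
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_rxc <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2 || any(m < 0)) {
    stop_alphapaf("need an r x c table (r, c >= 2) of non-negative counts",
                  "alphapaf_config_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_alphapaf("table has a zero margin", "alphapaf_config_error")
  }
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

# Robust Wald F-test of all non-intercept coefficients.
robust_wald_f <- function(fit, V) {
  cf <- stats::coef(fit)
  keep <- names(cf) != "(Intercept)"
  if (!any(keep)) return(list(F = NA_real_, p = NA_real_))
  R <- diag(length(cf))[keep, , drop = FALSE]
  q <- nrow(R)
  df2 <- fit$df.residual
  Fstat <- drop(t(R %*% cf) %*% solve(R %*% V %*% t(R)) %*% (R %*% cf)) / q
  list(F = Fstat, p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

#' OLS with heteroscedasticity-robust standard errors
#'
#' Ordinary least-squares point estimates with sandwich
#' (heteroscedasticity-consistent) standard errors, t statistics on the
#' residual degrees of freedom, 95% confidence intervals, a robust Wald F
#' test of the non-intercept terms, and R-squared.
#'
#' @param formula Model formula.
#' @param data Data frame; rows with missing values are dropped listwise.
#' @param se_flavor `"HC1"` (default), `"HC0"`, or `"HC3"`.
#'
#' @return An object of class `regression_result`: a list with a `terms`
#'   data frame (`term`, `coeff`, `robust_se`, `t`, `df`, `p`, `ci_lo`,
#'   `ci_hi`), plus `n`, `r_squared`, `f_statistic`, `f_p`.
#' @export
fit_ols_robust <- function(formula, data, se_flavor = c("HC1", "HC0", "HC3")) {
  se_flavor <- match.arg(se_flavor)
  data <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop_alphapaf(sprintf("rank-deficient design; aliased terms: %s",
                          paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                                collapse = ", ")),
                  "alphapaf_config_error")
  }
  if (fit$df.residual <= 0) {
    stop_alphapaf("no residual degrees of freedom", "alphapaf_config_error")
  }
  V <- sandwich::vcovHC(fit, type = se_flavor)
  ct <- lmtest::coeftest(fit, vcov. = V)
  crit <- stats::qt(0.975, fit$df.residual)
  terms <- data.frame(
    term = rownames(ct), coeff = ct[, 1], robust_se = ct[, 2],
    t = ct[, 3], df = fit$df.residual, p = ct[, 4],
    ci_lo = ct[, 1] - crit * ct[, 2], ci_hi = ct[, 1] + crit * ct[, 2],
    stringsAsFactors = FALSE
  )
  rownames(terms) <- NULL
  wf <- robust_wald_f(fit, V)
  structure(
    list(terms = terms, n = nrow(data),
         r_squared = summary(fit)$r.squared,
         f_statistic = wf$F, f_p = wf$p, se_flavor = se_flavor, lm_fit = fit),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n=%d, R2=%.3f, robust F p=%.4g (%s SEs)\n",
              x$n, x$r_squared, x$f_p, x$se_flavor))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg step-up decision
#'
#' Applies the Benjamini-Hochberg step-up rule at level `q` to one family of
#' p-values: reject all `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param q False discovery rate (default 0.05).
#'
#' @return List with `p`, `q`, `p_adjusted`, `reject` (logical, same order
#'   as input).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) {
    return(list(p = numeric(), q = q, p_adjusted = numeric(),
                reject = logical()))
  }
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop_alphapaf("p-values must lie in [0, 1]", "alphapaf_config_error")
  }
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(p = pvalues, q = q, p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

join_region_metadata <- function(region_table, metadata) {
  md <- metadata
  if (!"diagnosis" %in% names(md)) {
    md$diagnosis <- ifelse(md$group == "ASD", 1, 0)
  }
  merge(region_table, md, by = "subject_id")
}

#' Per-region moderator-by-diagnosis regression scan
#'
#' For each of the ten regions fits
#' `paf_hz ~ diagnosis + moderator + diagnosis:moderator` (diagnosis coded
#' ASD = 1, TD = 0) by OLS with heteroscedasticity-robust standard errors,
#' then applies Benjamini-Hochberg FDR control across the ten p-values of
#' the focal term (the interaction by default).
#'
#' @param region_table Output of [aggregate_regions()].
#' @param metadata Subject metadata with `subject_id`, `group` and the
#'   moderator column.
#' @param moderator One of `"age_months"`, `"srs_total"`, `"mps"`, `"ach"`
#'   (any metadata column works).
#' @param focal `"interaction"` (default) or `"moderator"`: which term's
#'   p-values form the FDR family.
#' @param q FDR level (default 0.05).
#' @param se_flavor Robust SE flavor, see [fit_ols_robust()].
#' @param min_n Regions with fewer complete cases are skipped (default 6).
#'
#' @return List with `results` (named list of `regression_result`), `scan`
#'   (data frame: region, focal coeff/se/t/df/p, `fdr_reject`), and `fdr`.
#' @export
region_interaction_scan <- function(region_table, metadata,
                                    moderator = "age_months",
                                    focal = c("interaction", "moderator"),
                                    q = 0.05, se_flavor = "HC1", min_n = 6) {
  focal <- match.arg(focal)
  df <- join_region_metadata(region_table, metadata)
  if (!moderator %in% names(df)) {
    stop_alphapaf(sprintf("moderator column `%s` not found", moderator),
                  "alphapaf_config_error")
  }
  fml <- stats::as.formula(paste("paf_hz ~ diagnosis *", moderator))
  focal_term <- if (focal == "interaction") {
    paste0("diagnosis:", moderator)
  } else moderator
  results <- list()
  rows <- list()
  for (reg in region_labels()) {
    sub <- df[df$region == reg, , drop = FALSE]
    sub <- sub[stats::complete.cases(sub[, c("paf_hz", "diagnosis", moderator)]), ]
    if (nrow(sub) < min_n) {
      message(sprintf("region %s skipped: %d complete cases (< %d)",
                      reg, nrow(sub), min_n))
      next
    }
    res <- fit_ols_robust(fml, sub, se_flavor = se_flavor)
    results[[reg]] <- res
    tr <- res$terms[res$terms$term == focal_term, ]
    rows[[reg]] <- data.frame(region = reg, term = focal_term,
                              coeff = tr$coeff, robust_se = tr$robust_se,
                              t = tr$t, df = tr$df, p = tr$p,
                              ci_lo = tr$ci_lo, ci_hi = tr$ci_hi,
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop_alphapaf("no region had enough complete cases", "alphapaf_config_error")
  }
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  fdr <- bh_fdr(scan$p, q = q)
  scan$p_adjusted <- fdr$p_adjusted
  scan$fdr_reject <- fdr$reject
  list(results = results, scan = scan, fdr = fdr)
}

#' Within-group simple regression for one region
#'
#' Follow-up model fitted separately within one diagnosis group:
#' `paf_hz ~ predictor`, with robust standard errors.
#'
#' @param region_table Output of [aggregate_regions()].
#' @param metadata Subject metadata.
#' @param region One of [region_labels()].
#' @param group `"ASD"` or `"TD"`.
#' @param predictor Metadata column name (default `"age_months"`).
#' @param se_flavor Robust SE flavor.
#'
#' @return A `regression_result`.
#' @export
per_group_regression <- function(region_table, metadata, region,
                                 group = c("ASD", "TD"),
                                 predictor = "age_months",
                                 se_flavor = "HC1") {
  group <- match.arg(group)
  df <- join_region_metadata(region_table, metadata)
  sub <- df[df$region == region & df$group == group, , drop = FALSE]
  sub <- sub[stats::complete.cases(sub[, c("paf_hz", predictor)]), ]
  if (nrow(sub) < 3L) {
    stop_alphapaf(sprintf("group %s has %d usable subjects in %s (< 3)",
                          group, nrow(sub), region),
                  "alphapaf_config_error")
  }
  if (stats::sd(sub[[predictor]]) == 0) {
    stop_alphapaf(sprintf("predictor `%s` is constant within group %s",
                          predictor, group),
                  "alphapaf_config_error")
  }
  fit_ols_robust(stats::as.formula(paste("paf_hz ~", predictor)), sub,
                 se_flavor = se_flavor)
}

#' Uncorrected SRS-subscale exploration for one region
#'
#' Fits one simple regression of regional PAF on each listed subscale
#' (uncorrected, significance flagged at `alpha`), the exploratory follow-up
#' used when a total-score effect is found in a region.
#'
#' @param region_table Output of [aggregate_regions()].
#' @param metadata Subject metadata containing the subscale columns.
#' @param region Region to model (default `"right_temporal"`).
#' @param subscales Character vector of subscale column names.
#' @param alpha Uncorrected significance level (default 0.05).
#' @param se_flavor Robust SE flavor.
#'
#' @return Data frame with one row per subscale: coefficient, robust SE, t,
#'   df, p, `significant`.
#' @export
subscale_scan <- function(region_table, metadata, region = "right_temporal",
                          subscales = c("srs_awareness", "srs_cognition",
                                        "srs_communication", "srs_motivation",
                                        "srs_mannerism"),
                          alpha = 0.05, se_flavor = "HC1") {
  missing_cols <- setdiff(subscales, names(metadata))
  if (length(missing_cols)) {
    stop_alphapaf(sprintf("metadata is missing subscale columns: %s",
                          paste(missing_cols, collapse = ", ")),
                  "alphapaf_config_error")
  }
  df <- join_region_metadata(region_table, metadata)
  sub <- df[df$region == region, , drop = FALSE]
  rows <- lapply(subscales, function(sc) {
    dat <- sub[stats::complete.cases(sub[, c("paf_hz", sc)]), ]
    if (stats::sd(dat[[sc]]) == 0) {
      stop_alphapaf(sprintf("subscale `%s` is constant", sc),
                    "alphapaf_config_error")
    }
    res <- fit_ols_robust(stats::as.formula(paste("paf_hz ~", sc)), dat,
                          se_flavor = se_flavor)
    tr <- res$terms[res$terms$term == sc, ]
    data.frame(subscale = sc, coeff = tr$coeff, robust_se = tr$robust_se,
               t = tr$t, df = tr$df, p = tr$p,
               significant = tr$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed model of a regional outcome by region and diagnosis
#'
#' Fits `outcome ~ region * diagnosis + (1 | subject_id)` by REML with the
#' reference region releveled to `reference_region`, and reports Wald z
#' statistics for the fixed effects. If the random-intercept variance is
#' estimated as singular (zero), the model falls back to OLS with
#' cluster-robust (by subject) standard errors and a warning.
#'
#' @param long_table Data frame with columns `subject_id`, `region`,
#'   `diagnosis` (ASD = 1 / TD = 0, or a `group` column), and the outcome.
#' @param outcome Column name, `"paf_hz"` or `"rel_alpha"`.
#' @param reference_region Reference level (default `"left_cingulate"`).
#'
#' @return An object of class `regression_result` whose `terms` carry
#'   columns `term`, `coeff`, `se`, `z`, `p`; the `fit` element holds the
#'   underlying model object, and `singular_fallback` records whether the
#'   OLS fallback was used.
#' @export
fit_lmm_region_diagnosis <- function(long_table, outcome = "paf_hz",
                                     reference_region = "left_cingulate") {
  df <- long_table
  if (!"diagnosis" %in% names(df)) {
    df$diagnosis <- ifelse(df$group == "ASD", 1, 0)
  }
  stopifnot(all(c("subject_id", "region", outcome) %in% names(df)))
  df <- df[stats::complete.cases(df[, c("subject_id", "region", "diagnosis", outcome)]), ]
  if (length(unique(df$region)) < 2L || length(unique(df$subject_id)) < 2L) {
    stop_alphapaf("need at least 2 regions and 2 subjects", "alphapaf_config_error")
  }
  df$region <- stats::relevel(factor(df$region), ref = reference_region)
  fml <- stats::as.formula(paste(outcome, "~ region * diagnosis + (1 | subject_id)"))
  fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("singular random-intercept variance; falling back to OLS with cluster-robust SEs")
    ofml <- stats::as.formula(paste(outcome, "~ region * diagnosis"))
    ofit <- stats::lm(ofml, data = df)
    V <- sandwich::vcovCL(ofit, cluster = df$subject_id)
    ct <- lmtest::coeftest(ofit, vcov. = V)
    terms <- data.frame(term = rownames(ct), coeff = ct[, 1], se = ct[, 2],
                        z = ct[, 3], p = 2 * stats::pnorm(-abs(ct[, 3])),
                        stringsAsFactors = FALSE)
    model <- ofit
  } else {
    ct <- summary(fit)$coefficients
    z <- ct[, "t value"]
    terms <- data.frame(term = rownames(ct), coeff = ct[, "Estimate"],
                        se = ct[, "Std. Error"], z = z,
                        p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
    model <- fit
  }
  rownames(terms) <- NULL
  structure(
    list(terms = terms, n = nrow(df), fit = model,
         singular_fallback = singular),
    class = "regression_result"
  )
}

#' Group descriptives in the style of a participants table
#'
#' Per-group n, mean, SD and range of the continuous subject variables, plus
#' pooled t-tests (TD minus ASD) and the sex-distribution chi-square.
#'
#' @param metadata Subject metadata from [simulate_cohort()] or equivalent.
#' @param variables Continuous columns to summarize.
#'
#' @return List with `continuous` (one row per variable) and `sex`
#'   (chi-square result plus percentages).
#' @export
cohort_descriptives <- function(metadata,
                                variables = c("age_months", "srs_total",
                                              "mps", "ach")) {
  asd <- metadata[metadata$group == "ASD", ]
  td <- metadata[metadata$group == "TD", ]
  rows <- lapply(variables, function(v) {
    tt <- two_sample_t(x = asd[[v]], y = td[[v]])
    data.frame(
      variable = v,
      asd_mean = mean(asd[[v]]), asd_sd = stats::sd(asd[[v]]),
      td_mean = mean(td[[v]]), td_sd = stats::sd(td[[v]]),
      t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE
    )
  })
  sex_tab <- c(a = sum(asd$sex == "M"), b = sum(asd$sex == "F"),
               c = sum(td$sex == "M"), d = sum(td$sex == "F"))
  sex <- suppressWarnings(
    chi_square_2x2(sex_tab["a"], sex_tab["b"], sex_tab["c"], sex_tab["d"],
                   correct = FALSE)
  )
  sex$pct_male_asd <- round(100 * sex_tab["a"] / nrow(asd), 1)
  sex$pct_male_td <- round(100 * sex_tab["c"] / nrow(td), 1)
  list(continuous = do.call(rbind, rows), sex = sex,
       n = c(ASD = nrow(asd), TD = nrow(td)))
}
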