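# Inferential layer: Gaussian linear mixed models on 1-5 discomfort codes
# with observer-level random effects, likelihood-ratio model comparison,
# Tukey contrasts between metric levels, bootstrap Spearman machinery, and
# the two-sample Kolmogorov-Smirnov comparison of stimulus sets.

#' Remove observers with zero rating variance
#'
#' Observers who give the same rating to every image carry no information
#' about the stimuli and are taken not to have engaged with the task.
#'
#' @param ratings Data frame with columns observer_id, image_id, rating.
#' @return List with `ratings` (rows of retained observers) and `excluded`
#'   (character vector of removed observer ids).
#' @export
exclude_invariant_observers <- function(ratings) {
  stopifnot(all(c("observer_id", "image_id", "rating") %in% names(ratings)))
  v <- tapply(ratings$rating, ratings$observer_id, stats::var)
  bad <- names(v)[!is.na(v) & v == 0]
  if (length(bad))
    message(sprintf("excluding %d invariant observer(s): %s", length(bad),
                    paste(bad, collapse = ", ")))
  list(ratings = ratings[!(ratings$observer_id %in% bad), , drop = FALSE],
       excluded = bad)
}

#' Fit a linear mixed model of discomfort ratings
#'
#' Gaussian LMM on numeric 1-5 ratings with a random intercept per
#' observer and, when `random_slopes = TRUE` (the default), a correlated
#' random slope per observer for each numeric fixed covariate. Numeric
#' covariates are standardized across images before fitting (their raw
#' scale is arbitrary), and slopes are reported on both scales. Fits use
#' maximum likelihood (`REML = FALSE`) so nested fits can enter
#' likelihood-ratio tests. Factor covariates (e.g. a low/medium/high metric
#' level) are used as-is and contribute a random intercept only.
#'
#' @param ratings Data frame with observer_id, image_id, rating, and one
#'   column per covariate named in `fixed`.
#' @param fixed Character vector of covariate column names (may be empty
#'   for the intercept-only null model).
#' @param random_slopes Include correlated per-observer random slopes for
#'   the numeric fixed covariates.
#' @param extra_random Optional character vector of extra grouping columns
#'   given random intercepts (e.g. `"triple_id"`).
#' @param standardize Standardize numeric covariates before fitting.
#' @return Object of class `discomfort_fit`: the `lme4` model plus
#'   fixed-effect estimates with 95% Wald CIs (`fixed_effects`), raw-scale
#'   slopes (`slopes_raw`), variance components (`varcorr`), `logLik`,
#'   `AIC`, `BIC`, `n_params`, and `singular` flag.
#' @export
fit_discomfort_lmm <- function(ratings, fixed = character(0),
                               random_slopes = TRUE,
                               extra_random = character(0),
                               standardize = TRUE) {
  stopifnot(all(c("observer_id", "rating") %in% names(ratings)))
  dat <- as.data.frame(ratings)
  dat$observer_id <- factor(dat$observer_id)
  if (nlevels(dat$observer_id) < 2) stop("need >= 2 observers", call. = FALSE)
  numeric_fixed <- fixed[vapply(fixed, function(f) is.numeric(dat[[f]]),
                                logical(1))]
  scales <- list()
  if (standardize) for (f in numeric_fixed) {
    # z-score across images (one value per image), not across rows, so the
    # scale does not depend on how many observers rated each image
    vals <- if ("image_id" %in% names(dat))
      tapply(dat[[f]], dat$image_id, function(v) v[1]) else dat[[f]]
    scales[[f]] <- c(center = mean(vals), sd = stats::sd(vals))
    dat[[f]] <- (dat[[f]] - scales[[f]]["center"]) / scales[[f]]["sd"]
  }
  fe <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  re_obs <- if (random_slopes && length(numeric_fixed))
    sprintf("(1 + %s | observer_id)", paste(numeric_fixed, collapse = " + "))
  else "(1 | observer_id)"
  re_extra <- if (length(extra_random))
    paste(sprintf("(1 | %s)", extra_random), collapse = " + ")
  fml <- stats::as.formula(paste(c(sprintf("rating ~ %s", fe), re_obs,
                                   re_extra), collapse = " + "))
  model <- lme4::lmer(fml, data = dat, REML = FALSE)
  singular <- lme4::isSingular(model)
  if (singular)
    warning("singular mixed-model fit (some variance components at zero)")
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  fixed_effects <- data.frame(
    term = names(est), estimate = as.numeric(est), se = se,
    ci_lo = as.numeric(est) - 1.96 * se, ci_hi = as.numeric(est) + 1.96 * se,
    row.names = NULL)
  slopes_raw <- stats::setNames(
    vapply(numeric_fixed,
           function(f) unname(est[f]) / if (standardize) scales[[f]]["sd"] else 1,
           numeric(1)),
    numeric_fixed)
  ll <- stats::logLik(model)
  structure(list(model = model, formula = fml, fixed = fixed,
                 fixed_effects = fixed_effects, slopes_raw = slopes_raw,
                 scales = scales,
                 varcorr = lme4::VarCorr(model),
                 logLik = as.numeric(ll), n_params = attr(ll, "df"),
                 AIC = stats::AIC(model), BIC = stats::BIC(model),
                 singular = singular),
            class = "discomfort_fit")
}

#' @export
print.discomfort_fit <- function(x, ...) {
  cat("Discomfort linear mixed model:",
      deparse(x$formula), "\n")
  cat(sprintf("logLik %.2f | AIC %.1f | BIC %.1f | params %d%s\n",
              x$logLik, x$AIC, x$BIC, x$n_params,
              if (x$singular) " | singular" else ""))
  print(x$fixed_effects, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' chi2 = 2 (logLik_full - logLik_null), compared against a chi-squared
#' distribution with df equal to the parameter-count difference. Both fits
#' must be maximum-likelihood fits on the same data. Identical models give
#' chi2 = 0, p = 1.
#'
#' @param null,full `discomfort_fit` objects, null nested in full.
#' @return List with `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(null, full) {
  stopifnot(inherits(null, "discomfort_fit"), inherits(full, "discomfort_fit"))
  chi2 <- 2 * (full$logLik - null$logLik)
  df <- full$n_params - null$n_params
  if (chi2 < -1e-6 || df < 0)
    stop("models do not appear to be nested (negative chi2 or df)",
         call. = FALSE)
  chi2 <- max(chi2, 0)
  p <- if (df == 0) {
    if (chi2 < 1e-8) 1 else stop("zero df with nonzero chi2", call. = FALSE)
  } else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Tukey-adjusted pairwise contrasts between factor levels
#'
#' Single-step multiplicity-adjusted comparisons of all level pairs of a
#' factor fixed effect, using the joint normal distribution of the
#' contrasts (multcomp's glht on the fitted lme4 model).
#'
#' @param fit A `discomfort_fit` whose model contains `factor_name` as a
#'   fixed factor.
#' @param factor_name Name of the factor column (default "level").
#' @return Data frame: contrast, estimate, se, z, p_adj.
#' @export
tukey_level_contrasts <- function(fit, factor_name = "level") {
  stopifnot(inherits(fit, "discomfort_fit"))
  linfct <- do.call(multcomp::mcp,
                    stats::setNames(list("Tukey"), factor_name))
  g <- summary(multcomp::glht(fit$model, linfct = linfct))
  data.frame(contrast = names(g$test$coefficients),
             estimate = as.numeric(g$test$coefficients),
             se = as.numeric(g$test$sigma),
             z = as.numeric(g$test$tstat),
             p_adj = as.numeric(g$test$pvalues),
             row.names = NULL)
}

#' Spearman correlation with bootstrap percentile confidence interval
#'
#' Resamples (x, y) pairs `B` times with the stated seed and reports the
#' 2.5% and 97.5% percentiles of the resampled correlations. An undefined
#' correlation (zero variance in either vector) is returned as NA, never
#' silently as 0.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param B Number of bootstrap replicates (>= 100; 10000 for final
#'   inference).
#' @param seed Integer seed.
#' @return List with `rho`, `ci_lo`, `ci_hi` and the replicate vector
#'   `boot`.
#' @export
spearman_bootstrap <- function(x, y, B = 10000, seed = 1L) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3, B >= 100)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                boot = rep(NA_real_, B)))
  rho <- stats::cor(x, y, method = "spearman")
  boot <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    vapply(seq_len(B), function(b) {
      i <- idx[, b]
      suppressWarnings(stats::cor(x[i], y[i], method = "spearman"))
    }, numeric(1))
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(rho = rho, ci_lo = ci[1], ci_hi = ci[2], boot = boot)
}

#' Bootstrap test for a difference between two Spearman correlations
#'
#' Both correlations share the same items: rho1 = cor(x, y1) and
#' rho2 = cor(x, y2) are recomputed on each paired resample, and the
#' two-sided p-value is twice the smaller tail probability of the
#' resampled difference crossing zero, capped at 1.
#'
#' @param x Common covariate vector.
#' @param y1,y2 Outcome vectors paired with `x`.
#' @param B Number of replicates.
#' @param seed Integer seed.
#' @return List with `rho1`, `rho2`, `diff`, `p`.
#' @export
spearman_difference_test <- function(x, y1, y2, B = 10000, seed = 1L) {
  n <- length(x)
  stopifnot(n == length(y1), n == length(y2), n >= 3, B >= 100)
  rho1 <- suppressWarnings(stats::cor(x, y1, method = "spearman"))
  rho2 <- suppressWarnings(stats::cor(x, y2, method = "spearman"))
  d <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    vapply(seq_len(B), function(b) {
      i <- idx[, b]
      suppressWarnings(
        stats::cor(x[i], y1[i], method = "spearman") -
        stats::cor(x[i], y2[i], method = "spearman"))
    }, numeric(1))
  })
  d <- d[is.finite(d)]
  p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  list(rho1 = rho1, rho2 = rho2, diff = rho1 - rho2, p = p)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic two-sample formula.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}
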