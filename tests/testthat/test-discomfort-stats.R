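make_ratings <- function(n_obs = 6, n_img = 8, seed = 1) {
  withr::with_seed(seed, {
    metric <- runif(n_img)
    simulate_ratings(metric, observer_model(), n_observers = n_obs,
                     seed = seed + 1)
  })
}

test_that("invariant observers are excluded, variable ones retained", {
  r <- make_ratings()
  flat <- data.frame(observer_id = "flat", image_id = unique(r$image_id),
                     rating = 3L, metric = unique(r$metric))
  res <- suppressMessages(exclude_invariant_observers(rbind(r, flat)))
  expect_equal(res$excluded, "flat")
  expect_false("flat" %in% res$ratings$observer_id)
  res2 <- exclude_invariant_observers(r)
  expect_identical(res2$ratings, r)
  expect_length(res2$excluded, 0)
})

test_that("noiseless identical observers reduce to pooled least squares", {
  n_img <- 12
  withr::with_seed(121, metric <- runif(n_img))
  z <- as.numeric(scale(metric))
  lat <- 3 + 0.4 * z
  dat <- expand.grid(observer_id = sprintf("o%d", 1:4),
                     image_id = sprintf("i%d", 1:n_img))
  dat$metric <- metric[match(dat$image_id, sprintf("i%d", 1:n_img))]
  dat$rating <- lat[match(dat$image_id, sprintf("i%d", 1:n_img))]
  fit <- suppressWarnings(fit_discomfort_lmm(dat, "metric"))
  ols <- coef(lm(lat ~ z))
  expect_equal(fit$fixed_effects$estimate[2], unname(ols[2]),
               tolerance = 1e-6)
  vc <- as.data.frame(fit$varcorr)
  expect_lt(max(vc$vcov), 1e-6)
})

test_that("information-criterion identities hold for every fit", {
  r <- make_ratings(8, 10, seed = 3)
  for (rs in c(TRUE, FALSE)) {
    fit <- suppressWarnings(fit_discomfort_lmm(r, "metric",
                                               random_slopes = rs))
    expect_equal(fit$AIC, 2 * fit$n_params - 2 * fit$logLik,
                 tolerance = 1e-8)
    n <- nrow(r)
    expect_equal(fit$BIC, log(n) * fit$n_params - 2 * fit$logLik,
                 tolerance = 1e-8)
  }
})

test_that("LRT: df bookkeeping, identical models, rescaling invariance", {
  r <- make_ratings(10, 12, seed = 5)
  null <- fit_discomfort_lmm(r, character(0))
  full <- suppressWarnings(fit_discomfort_lmm(r, "metric"))
  lrt <- likelihood_ratio_test(null, full)
  # adding one covariate plus its correlated random slope: df = 3
  expect_equal(lrt$df, 3)
  expect_gte(lrt$chi2, 0)

  same <- likelihood_ratio_test(null, null)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # affine rescaling of the covariate leaves chi2 unchanged
  r2 <- r; r2$metric <- 1000 * r2$metric - 7
  full2 <- suppressWarnings(fit_discomfort_lmm(r2, "metric"))
  expect_equal(likelihood_ratio_test(null, full2)$chi2, lrt$chi2,
               tolerance = 1e-6)

  expect_error(likelihood_ratio_test(full, null), "nested")
})

test_that("Tukey contrasts recover a constructed low << medium ~ high pattern", {
  n_obs <- 20; n_tr <- 12
  withr::with_seed(131, {
    dat <- expand.grid(observer_id = sprintf("o%02d", 1:n_obs),
                       triple_id = sprintf("t%02d", 1:n_tr),
                       level = c("low", "medium", "high"))
    eff <- c(low = 1.6, medium = 2.6, high = 2.65)
    dat$rating <- eff[as.character(dat$level)] +
      rnorm(n_obs, 0, 0.3)[match(dat$observer_id, sprintf("o%02d", 1:n_obs))] +
      rnorm(nrow(dat), 0, 0.5)
    dat$level <- factor(dat$level, levels = c("low", "medium", "high"))
  })
  fit <- suppressWarnings(
    fit_discomfort_lmm(dat, "level", extra_random = "triple_id"))
  tk <- tukey_level_contrasts(fit)
  expect_equal(nrow(tk), 3)
  p <- setNames(tk$p_adj, tk$contrast)
  expect_lt(p[["medium - low"]], 0.05)
  expect_lt(p[["high - low"]], 0.05)
  expect_gt(p[["high - medium"]], 0.05)

  # literally identical groups (each observer repeats the same responses
  # at every level): contrasts are exactly zero, all adjusted p ~ 1
  withr::with_seed(132, {
    dat0 <- dat
    base <- 2 + rnorm(n_obs * n_tr, 0, 0.5)
    dat0$rating <- rep(base, times = 3)
  })
  fit0 <- suppressWarnings(fit_discomfort_lmm(dat0, "level",
                                              extra_random = "triple_id"))
  expect_true(all(suppressWarnings(tukey_level_contrasts(fit0))$p_adj > 0.95))
})

test_that("Spearman bootstrap matches hand-ranked values and brackets rho", {
  expect_equal(spearman_bootstrap(1:10, 1:10, B = 100, seed = 1)$rho, 1)
  expect_equal(spearman_bootstrap(1:10, 10:1, B = 100, seed = 1)$rho, -1)
  # rank enumeration: d = (0,-1,1,-1,1), rho = 1 - 6*4/120
  bs <- spearman_bootstrap(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4),
                           B = 200, seed = 2)
  expect_equal(bs$rho, 1 - 6 * 4 / (5 * 24))
  expect_equal(bs$rho, 0.8)

  withr::with_seed(141, {
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  })
  bs2 <- spearman_bootstrap(x, y, B = 500, seed = 3)
  expect_true(bs2$ci_lo <= bs2$rho && bs2$rho <= bs2$ci_hi)
  # ties everywhere: undefined, flagged NA
  expect_true(is.na(spearman_bootstrap(rep(1, 5), 1:5, B = 100,
                                       seed = 1)$rho))
  expect_error(spearman_bootstrap(1:2, 1:2, B = 100))
})

test_that("Spearman difference test: null self-comparison and power", {
  withr::with_seed(151, {
    x <- rnorm(50)
    y1 <- x + rnorm(50, 0, 0.3)   # strongly related
    y2 <- rnorm(50)               # unrelated
  })
  expect_equal(spearman_difference_test(x, y1, y1, B = 200, seed = 1)$p, 1)
  hits <- vapply(1:10, function(s)
    spearman_difference_test(x, y1, y2, B = 400, seed = s)$p < 0.05,
    logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("KS statistic matches ECDF enumeration", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(1:5, 101:105)$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D, 1 / 3,
               tolerance = 1e-12)
})
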