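test_that("noiseless data recovers coefficients exactly with both variances at zero", {
  d <- expand.grid(country = sprintf("C%d", 1:4), year = 2000:2005,
                   stringsAsFactors = FALSE)
  d$developing <- as.numeric(d$country %in% c("C3", "C4"))
  d$flp <- 12 - 6 * d$developing + 0.3 * (d$year - 2000)
  fit <- fit_random_intercept_lmm(d)
  expect_equal(fit$coefficients$estimate, c(12, -6, 0.3))
  expect_equal(fit$sigma_u, 0)
  expect_equal(fit$sigma_e, 0)
  expect_true(fit$boundary)
})

test_that("ML estimates match a dense grid-search maximizer of the exact likelihood", {
  cases <- list(
    list(n_countries = 4, obs = 3, sigma_u = 3, sigma_e = 4, seed = 1),
    list(n_countries = 6, obs = 5, sigma_u = 2, sigma_e = 1, seed = 2),
    list(n_countries = 10, obs = 5, sigma_u = 0, sigma_e = 5, seed = 3),
    list(n_countries = 5, obs = 6, sigma_u = 6, sigma_e = 2, seed = 4))
  for (cs in cases) {
    d <- make_lmm_data(cs$n_countries, cs$obs, sigma_u = cs$sigma_u,
                       sigma_e = cs$sigma_e, seed = cs$seed)
    expect_lte(nrow(d), 50)
    fit <- fit_random_intercept_lmm(d)
    X <- cbind(1, d$developing, d$year - 2000)
    oracle <- grid_ml_oracle(X, d$flp, d$country)
    expect_equal(fit$sigma_u, oracle$sigma_u, tolerance = 1e-4)
    expect_equal(fit$sigma_e, oracle$sigma_e, tolerance = 1e-4)
    expect_equal(fit$coefficients$estimate, unname(oracle$beta),
                 tolerance = 1e-4)
    expect_equal(fit$logLik, oracle$logLik, tolerance = 1e-6)
  }
})

test_that("profiled ML agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- make_lmm_data(12, 6, sigma_u = 3, sigma_e = 4, seed = 7)
  fit <- fit_random_intercept_lmm(d)
  ref <- lme4::lmer(flp ~ developing + I(year - 2000) + (1 | country),
                    data = d, REML = FALSE)
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(ref)),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma_u, vc$sdcor[vc$grp == "country"], tolerance = 1e-4)
  expect_equal(fit$sigma_e, vc$sdcor[vc$grp == "Residual"], tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(as.matrix(stats::vcov(ref))))),
               tolerance = 1e-4)
})

test_that("forcing the country variance to zero reproduces OLS exactly", {
  d <- make_lmm_data(5, 4, seed = 11)
  fit <- fit_random_intercept_lmm(d, force_sigma_u_zero = TRUE)
  ols <- stats::lm(flp ~ developing + I(year - 2000), data = d)
  sm <- summary(ols)$coefficients
  expect_equal(fit$coefficients$estimate, unname(sm[, 1]))
  expect_equal(fit$coefficients$se, unname(sm[, 2]))
  expect_equal(fit$sigma_u, 0)
})

test_that("shifting the centering year moves only the intercept", {
  d <- make_lmm_data(8, 5, seed = 13)
  f1 <- fit_random_intercept_lmm(d, center = 2000)
  f2 <- fit_random_intercept_lmm(d, center = 2010)
  expect_equal(f1$coefficients$estimate[2:3], f2$coefficients$estimate[2:3],
               tolerance = 1e-8)
  expect_equal(f1$sigma_u, f2$sigma_u, tolerance = 1e-6)
  expect_equal(f1$sigma_e, f2$sigma_e, tolerance = 1e-6)
  expect_equal(f1$r2_marginal, f2$r2_marginal, tolerance = 1e-6)
  expect_equal(f1$r2_conditional, f2$r2_conditional, tolerance = 1e-6)
  expect_equal(f1$coefficients$estimate[1],
               f2$coefficients$estimate[1] - 10 * f1$coefficients$estimate[3],
               tolerance = 1e-6)
})

test_that("R-squared decomposition: bounds, boundary equality, and null limit", {
  d <- make_lmm_data(10, 6, sigma_u = 3, sigma_e = 4, seed = 17)
  fit <- fit_random_intercept_lmm(d)
  expect_gte(fit$r2_marginal, 0)
  expect_lte(fit$r2_marginal, fit$r2_conditional)
  expect_lte(fit$r2_conditional, 1)
  # sigma_u = 0 forces marginal == conditional
  f0 <- fit_random_intercept_lmm(d, force_sigma_u_zero = TRUE)
  expect_equal(f0$r2_marginal, f0$r2_conditional)
  # with no fixed effects in truth, marginal R2 is near zero at large n
  d0 <- make_lmm_data(60, 20, beta = c(15, 0, 0), sigma_u = 2, sigma_e = 4,
                      seed = 19)
  fnull <- fit_random_intercept_lmm(d0)
  expect_lt(fnull$r2_marginal, 0.02)
})

test_that("single-country data errors for the random intercept but batches survive", {
  d <- make_lmm_data(6, 4, seed = 23)
  single <- d[d$country == "C01", ]
  expect_error(fit_random_intercept_lmm(single), "single")

  rec <- d
  rec$commodity_group <- rep(c("grains", "oilseeds"), length.out = nrow(d))
  rec$commodity_group[rec$country == "C01"] <- "pulses"
  rec <- rec[!(rec$country != "C01" & rec$commodity_group == "pulses"), ]
  # pulses now has a single country: flagged, batch continues
  labels <- stats::setNames(ifelse(tapply(d$developing, d$country, max) == 1,
                                   "developing", "developed"),
                            names(tapply(d$developing, d$country, max)))
  out <- fit_all_strata(rec, labels, "commodity")
  expect_equal(nrow(out$table), 3L)
  expect_false(out$table$fitted[out$table$stratum == "pulses"])
  expect_true(all(out$table$fitted[out$table$stratum != "pulses"]))
})

test_that("one model is fit per synthetic commodity stratum", {
  sim <- generate_indicator_panel(indicator_sim_config(seed = 27))
  rec <- generate_flp_panel(flp_sim_config(seed = 28), sim$labels)$records
  scr <- apply_exclusions(categorize(rec)$records)
  out <- fit_all_strata(scr$records, sim$labels, "commodity")
  expect_equal(nrow(out$table), 10L)     # beverages screened out
  expect_true(all(out$table$fitted))
  expect_true(all(out$table$r2_marginal <= out$table$r2_conditional + 1e-12))
})

test_that("hypothesis report decides and signs both tests", {
  sim <- generate_indicator_panel(indicator_sim_config(seed = 29))
  betas <- data.frame(stratum = c("grains", "others"),
                      beta0 = c(20, 15), beta1 = c(-8, 0), beta2 = c(0, 0.3),
                      coverage = 1)
  rec <- generate_flp_panel(flp_sim_config(betas = betas, obs_per_cell = 5,
                                           miss_commodity = 0,
                                           miss_activity = 0, miss_flp = 0,
                                           seed = 30), sim$labels)$records
  out <- fit_all_strata(categorize(rec)$records, sim$labels, "commodity")
  rep <- hypothesis_report(out, alpha = 0.05)
  expect_true(rep$reject_development_null[rep$stratum == "grains"])
  expect_equal(rep$direction_development[rep$stratum == "grains"],
               "developing lower")
  expect_true(rep$reject_year_null[rep$stratum == "others"])
  expect_equal(rep$direction_year[rep$stratum == "others"], "increasing")
})

test_that("a strong year trend is detected in nearly every replicate", {
  sim_labels <- stats::setNames(rep(c("developed", "developing"), 15),
                                sprintf("C%02d", 1:30))
  betas <- data.frame(stratum = "grains", beta0 = 20, beta1 = -3,
                      beta2 = 0.3, coverage = 1)
  rejections <- vapply(1:50, function(s) {
    rec <- generate_flp_panel(
      flp_sim_config(betas = betas, sigma_u = 1, sigma_e = 2,
                     obs_per_cell = 8, miss_commodity = 0, miss_activity = 0,
                     miss_flp = 0, seed = 1000 + s), sim_labels)$records
    rec$commodity_group <- "grains"
    fit <- fit_all_strata(rec, sim_labels, "commodity")
    fit$table$p2 < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})
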