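test_that("an exactly linear series gives its slope with zero SE", {
  rec <- data.frame(country = "A", year = 2000:2006,
                    flp = 2 + 0.5 * (2000:2006 - 2000))
  fit <- trend_ols(rec)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$se, 0, tolerance = 1e-10)
  expect_equal(fit$p, 0)
  expect_true(fit$sufficient)
})

test_that("slope and SE match the closed-form OLS expressions", {
  withr::with_seed(55, {
    year <- c(2001, 2004, 2008, 2015, 2020)
    flp <- 10 + 0.4 * (year - 2000) + stats::rnorm(5, 0, 2)
  })
  fit <- trend_ols(data.frame(country = "A", year = year, flp = flp))
  # textbook formulas, computed independently
  x <- year - 2000
  b <- sum((x - mean(x)) * (flp - mean(flp))) / sum((x - mean(x))^2)
  a <- mean(flp) - b * mean(x)
  rss <- sum((flp - a - b * x)^2)
  se <- sqrt(rss / (length(x) - 2) / sum((x - mean(x))^2))
  expect_equal(fit$slope, b, tolerance = 1e-12)
  expect_equal(fit$se, se, tolerance = 1e-12)
  expect_equal(fit$p, 2 * stats::pt(-abs(b / se), df = 3), tolerance = 1e-12)
})

test_that("fewer than three distinct years yields an insufficient-years flag", {
  rec <- data.frame(country = "A", year = c(2000, 2000, 2003), flp = c(1, 2, 3))
  fit <- trend_ols(rec)
  expect_false(fit$sufficient)
  expect_true(is.na(fit$slope))
  expect_equal(fit$n, 3L)
})

test_that("group means: singleton cells, closed-form noiseless means, borderline columns", {
  labels <- c(A = "developed", B = "developing", H = "developing")
  rec <- data.frame(
    country = c("A", "A", "B", "B", "H"),
    year = c(2000, 2002, 2000, 2004, 2010),
    commodity_raw = "wheat", activity_raw = "storage",
    flp = c(10, 12, 4, 6, 42),
    commodity_group = "grains", activity_group = "storage",
    stringsAsFactors = FALSE)
  gm <- group_means(rec, labels, "commodity", borderline = "H")
  expect_equal(gm$mean_flp[gm$group == "H"], 42)   # singleton cell
  expect_equal(gm$mean_flp[gm$group == "developed"], 11)
  expect_equal(gm$mean_flp[gm$group == "developing"], 5)
  expect_setequal(unique(gm$group), c("developed", "developing", "H"))

  # noiseless generator: cell means equal beta0 + beta1 D + beta2 mean(t-2000)
  lab2 <- c(X = "developed", Y = "developing")
  betas <- data.frame(stratum = "grains", beta0 = 10, beta1 = -4,
                      beta2 = 0.5, coverage = 1)
  sim <- generate_flp_panel(flp_sim_config(betas = betas, sigma_u = 0,
                                           sigma_e = 0, obs_per_cell = 6,
                                           miss_commodity = 0,
                                           miss_activity = 0, miss_flp = 0,
                                           seed = 3), lab2)
  srec <- categorize(sim$records)$records
  gm2 <- group_means(srec, lab2, "commodity")
  for (g in c("developed", "developing")) {
    cell <- srec[unname(lab2[srec$country]) == g, ]
    d <- as.numeric(g == "developing")
    expect_equal(gm2$mean_flp[gm2$group == g],
                 10 - 4 * d + 0.5 * mean(cell$year - 2000))
  }
})

test_that("the overall mean equals the n-weighted mean of cell means", {
  sim <- generate_indicator_panel(indicator_sim_config(
    n_developed = 4, n_developing = 12, seed = 61))
  rec <- generate_flp_panel(flp_sim_config(miss_commodity = 0,
                                           miss_activity = 0, miss_flp = 0,
                                           seed = 62), sim$labels)$records
  rec <- categorize(rec)$records
  gm <- group_means(rec, sim$labels, "activity")
  overall <- mean(rec$flp[!is.na(rec$activity_group)])
  expect_equal(sum(gm$mean_flp * gm$n) / sum(gm$n), overall, tolerance = 1e-12)
})

test_that("trend_ols agrees with the mixed model at the zero-variance limit", {
  d <- make_lmm_data(5, 6, beta = c(14, 0, 0.4), sigma_u = 0, sigma_e = 2,
                     seed = 63, p_developing = 0)
  d$developing <- 0                      # single development group
  lmm <- fit_random_intercept_lmm(d, force_sigma_u_zero = TRUE)
  tr <- trend_ols(d)
  expect_equal(tr$slope,
               lmm$coefficients$estimate[lmm$coefficients$term == "year_centered"],
               tolerance = 1e-10)
  expect_equal(tr$se,
               lmm$coefficients$se[lmm$coefficients$term == "year_centered"],
               tolerance = 1e-10)
})

test_that("borderline profiles report coverage and warn about absent countries", {
  rec <- data.frame(country = rep("NZ", 5),
                    year = c(2000, 2000, 2001, 2002, 2003),
                    commodity_raw = "apples", activity_raw = "harvesting",
                    flp = c(8, 9, 8.5, 9.2, 8.8),
                    commodity_group = "fruits",
                    activity_group = "harvest and on-farm operations",
                    stringsAsFactors = FALSE)
  expect_warning(out <- borderline_profiles(rec, c("NZ", "Nowhere"),
                                            "commodity"),
                 "Nowhere")
  expect_equal(out$summary$n, c(5L, 0L))
  expect_equal(out$summary$n_years[1], 4L)
  expect_equal(out$summary$coverage_fraction[1], 4 / 23)
  expect_equal(out$stratum_means$mean_flp,
               mean(c(8, 9, 8.5, 9.2, 8.8)))
})
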