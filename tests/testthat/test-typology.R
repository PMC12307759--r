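test_that("temporal weights: uniform limit, geometric ratio, singleton, errors", {
  expect_equal(unname(temporal_weights(2000:2002, 0)), rep(1 / 3, 3),
               ignore_attr = TRUE)
  w <- temporal_weights(c(2000, 2001, 2002), 0.2)
  # direct evaluation: proportional to (1, e^0.2, e^0.4)
  expect_equal(unname(w), exp(0.2 * 0:2) / sum(exp(0.2 * 0:2)),
               ignore_attr = TRUE)
  expect_equal(w[[2]] / w[[1]], exp(0.2))
  expect_equal(w[[3]] / w[[2]], exp(0.2))
  expect_equal(unname(temporal_weights(2014, 0)), 1, ignore_attr = TRUE)
  expect_equal(unname(temporal_weights(2014, 5)), 1, ignore_attr = TRUE)
  expect_error(temporal_weights(integer(0), 0.1), "at least one")
  expect_error(temporal_weights(2000:2002, -0.1), "lambda")
})

test_that("weights sum to one and increase geometrically on random year sets", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      years <- sort(sample(1990:2022, sample(2:20, 1)))
      lambda <- stats::runif(1, 0, 0.5)
      w <- temporal_weights(years, lambda)
      expect_lt(abs(sum(w) - 1), 1e-12)
      expect_true(all(w > 0))
      consecutive <- which(diff(years) == 1)
      for (i in consecutive) {
        expect_equal(w[[i + 1]] / w[[i]], exp(lambda), tolerance = 1e-10)
      }
      if (lambda > 0) expect_true(all(diff(w) > 0))
    }
  })
})

test_that("weighted profiles are convex combinations with per-indicator renormalization", {
  panel <- data.frame(country = "A", year = 2000:2004, gdp_pc = 7,
                      health_pc = c(1, 2, 3, NA, NA),
                      growth = c(NA, NA, 1, 2, 3))
  prof <- weighted_profiles(panel, 0.2)
  expect_equal(prof$gdp_pc, 7)           # constant series is a fixed point
  # two-line oracle for values (1,2,3) at consecutive years, lambda = 0.2
  w <- exp(0.2 * 0:2) / sum(exp(0.2 * 0:2))
  expect_equal(prof$health_pc, sum(w * c(1, 2, 3)))
  expect_equal(prof$growth, sum(w * c(1, 2, 3)))   # renormalized over 2002:2004
  # convexity bound across random inputs
  withr::with_seed(5, {
    for (rep in 1:10) {
      vals <- stats::rnorm(6)
      p <- weighted_profiles(data.frame(country = "X", year = 2000:2005,
                                        gdp_pc = vals, health_pc = 1,
                                        growth = 1),
                             stats::runif(1, 0, 0.5))
      expect_gte(p$gdp_pc, min(vals))
      expect_lte(p$gdp_pc, max(vals))
    }
  })
})

test_that("very large lambda concentrates the profile on the latest year", {
  panel <- data.frame(country = "A", year = 2000:2010,
                      gdp_pc = seq(100, 200, by = 10), health_pc = 1,
                      growth = 1)
  prof <- weighted_profiles(panel, 50)
  expect_lt(abs(prof$gdp_pc - 200), 1e-6)
})

test_that("countries with an entirely missing indicator are dropped and logged", {
  panel <- data.frame(country = rep(c("A", "B"), each = 2), year = 2000:2001,
                      gdp_pc = c(1, 2, NA, NA), health_pc = 1, growth = 1)
  prof <- weighted_profiles(panel, 0.1)
  expect_equal(prof$country, "A")
  expect_equal(attr(prof, "dropped"), "B")
})

test_that("k-means matches the exhaustive-partition oracle on small instances", {
  # the canonical 1-D case: {0, 1, 10, 11} splits into {0,1} / {10,11}
  prof <- data.frame(country = letters[1:4], gdp_pc = c(0, 1, 10, 11),
                     health_pc = 0, growth = 0, n_years = 1)
  fit <- kmeans_fit(prof, 2, restarts = 10, seed = 1, standardize = FALSE)
  expect_equal(fit$wcss, 1.0)
  expect_equal(unname(fit$labels), c("developing", "developing",
                                     "developed", "developed"))
  oracle <- brute_kmeans_wcss(cbind(c(0, 1, 10, 11), 0, 0), 2)
  expect_equal(fit$wcss, oracle$wcss)

  withr::with_seed(17, {
    for (rep in 1:6) {
      n <- sample(5:9, 1)
      k <- sample(2:3, 1)
      x <- matrix(stats::rnorm(n * 3), n, 3)
      prof <- data.frame(country = sprintf("c%d", 1:n), gdp_pc = x[, 1],
                         health_pc = x[, 2], growth = x[, 3], n_years = 1)
      fit <- kmeans_fit(prof, k, restarts = 60, seed = rep,
                        standardize = FALSE)
      expect_equal(fit$wcss, brute_kmeans_wcss(x, k)$wcss, tolerance = 1e-8)
    }
  })
})

test_that("k = n gives zero WCSS and k > n errors", {
  prof <- data.frame(country = letters[1:4], gdp_pc = c(0, 1, 10, 11),
                     health_pc = c(5, 3, 2, 0), growth = 0, n_years = 1)
  fit <- kmeans_fit(prof, 4, restarts = 30, seed = 2, standardize = FALSE)
  expect_equal(fit$wcss, 0)
  expect_error(kmeans_fit(prof, 5, seed = 1), "exceeds")
})

test_that("the developed cluster has the highest GDP-per-capita centroid", {
  sim <- generate_indicator_panel(indicator_sim_config(
    n_developed = 5, n_developing = 20, seed = 6))
  prof <- weighted_profiles(sim$panel, 0.2)
  fit <- kmeans_fit(prof, 2, restarts = 20, seed = 3)
  expect_gt(fit$centroids["developed", "gdp_pc"],
            fit$centroids["developing", "gdp_pc"])
  expect_true(all(sort(unique(fit$labels)) == c("developed", "developing")))
})

test_that("cluster labels are invariant to input row order", {
  sim <- generate_indicator_panel(indicator_sim_config(
    n_developed = 4, n_developing = 16, seed = 23))
  prof <- weighted_profiles(sim$panel, 0.2)
  fit1 <- kmeans_fit(prof, 2, restarts = 25, seed = 7)
  shuffled <- weighted_profiles(sim$panel[sample(nrow(sim$panel)), ], 0.2)
  fit2 <- kmeans_fit(shuffled, 2, restarts = 25, seed = 7)
  expect_equal(fit2$labels[names(fit1$labels)], fit1$labels)
})

test_that("silhouette matches the brute-force pairwise formula", {
  x <- cbind(c(0, 0, 10, 10))
  expect_equal(silhouette_mean(x, c(1, 1, 2, 2)), 1.0)
  x2 <- cbind(c(0, 1, 5, 6))
  lab2 <- c("a", "a", "b", "b")
  expect_equal(silhouette_mean(x2, lab2), 79 / 99, tolerance = 1e-10)
  expect_equal(silhouette_mean(x2, lab2), brute_silhouette(x2, lab2),
               tolerance = 1e-10)
  expect_error(silhouette_mean(x2, rep(1, 4)), "two clusters")
  withr::with_seed(41, {
    for (rep in 1:10) {
      n <- sample(4:12, 1)
      x <- matrix(stats::rnorm(n * 2), n, 2)
      lab <- sample(1:3, n, replace = TRUE)
      if (length(unique(lab)) < 2) next
      expect_equal(silhouette_mean(x, lab), brute_silhouette(x, lab),
                   tolerance = 1e-10)
    }
  })
})

test_that("elbow curve starts at the total sum of squares and drops hardest at the true k", {
  sim <- generate_indicator_panel(indicator_sim_config(
    n_developed = 8, n_developing = 22, seed = 12))
  prof <- weighted_profiles(sim$panel, 0.2)
  curve <- elbow_curve(prof, 1:5, restarts = 20, seed = 2)
  x <- scale(as.matrix(prof[, c("gdp_pc", "health_pc", "growth")]))
  expect_equal(curve$wcss[1], sum(scale(x, scale = FALSE)^2))
  expect_true(all(diff(curve$wcss) <= 1e-8))
  expect_equal(which.max(curve$delta_wcss[-1]) + 1L, 2L)  # elbow at k = 2
})

test_that("select_configuration picks the best two-cluster lambda with ties toward smaller", {
  grid <- data.frame(lambda = c(0.0, 0.1, 0.2, 0.3),
                     suggested_k = c(2, 2, 2, 3),
                     silhouette_suggested = c(0.6, 0.7, 0.65, 0.9))
  expect_equal(select_configuration(grid, 2), 0.1)
  tie <- grid
  tie$silhouette_suggested <- c(0.6, 0.7, 0.7, 0.9)
  expect_equal(select_configuration(tie, 2), 0.1)
  # stable under reordering
  expect_equal(select_configuration(tie[c(3, 1, 4, 2), ], 2), 0.1)
  expect_error(select_configuration(grid, 6), "no lambda")
})

test_that("well-separated panels are fully stable across the lambda grid", {
  sim <- generate_indicator_panel(indicator_sim_config(
    n_developed = 6, n_developing = 24, seed = 14))
  sens <- sensitivity_analysis(sim$panel, seq(0, 0.5, 0.1),
                               reference_lambda = 0.2, k_candidates = 2:4,
                               restarts = 20, seed = 5)
  expect_true(all(sens$grid$agreement == 1))
  expect_true(all(sens$grid$n_changed == 0))
  expect_equal(sens$grid$agreement[abs(sens$grid$lambda - 0.2) < 1e-12], 1)
  report <- borderline_report(sens, sim$panel)
  expect_equal(nrow(report), 0L)
})

test_that("a constructed mid-gap country with late catch-up flips across the grid", {
  base <- generate_indicator_panel(indicator_sim_config(
    n_developed = 8, n_developing = 22, seed = 33,
    coverage_range = c(1, 1)))
  # early years deep in the developing cloud, last two years at the
  # developed centroid: low lambda sees history, high lambda the catch-up
  years <- 2000:2022
  gdp <- c(rep(5000, 21), 56000, 56000)
  health <- c(rep(260, 21), 5500, 5500)
  growth <- rep(2.5, 23)
  hybrid <- data.frame(country = "Hybridia", year = years, gdp_pc = gdp,
                       growth = growth, health_pc = health)
  panel <- rbind(base$panel, hybrid)
  sens <- sensitivity_analysis(panel, seq(0, 0.5, 0.1),
                               reference_lambda = 0, k_candidates = 2:3,
                               restarts = 20, seed = 9)
  report <- borderline_report(sens, panel)
  expect_true("Hybridia" %in% report$country)
  expect_match(report$direction[report$country == "Hybridia"],
               "developing -> developed")
  expect_true(all(setdiff(rownames(sens$labels_k2), "Hybridia") %in%
                    rownames(sens$labels_k2)[rowSums(sens$labels_k2 !=
                      sens$labels_k2[, 1]) == 0]))
})
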