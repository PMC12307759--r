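# Exponential temporal weighting of country indicator histories, K-means
# classification into developed/developing groups, silhouette/elbow
# validation, and the decay-parameter sensitivity and stability analysis.

#' Exponential temporal weights over a country's observed years
#'
#' For decay `lambda > 0` the weight of year t is proportional to
#' `exp(lambda * (t - min(t)))`, normalized to sum to one over the observed
#' years, so recent years receive geometrically more weight: consecutive
#' observed years satisfy `w[t+1] / w[t] = exp(lambda)`. `lambda = 0` is
#' defined as the exact uniform limit.
#'
#' @param years integer vector of observed years (duplicates collapsed).
#' @param lambda decay parameter, >= 0.
#' @return named numeric vector of weights over the sorted unique years,
#'   summing to 1, with attributes `lambda` and `origin` (the minimum year,
#'   which anchors the exponent at zero).
#' @export
temporal_weights <- function(years, lambda) {
  years <- sort(unique(as.integer(years)))
  if (length(years) == 0L || anyNA(years)) {
    stop("temporal_weights needs at least one observed year", call. = FALSE)
  }
  if (!is.finite(lambda) || lambda < 0) {
    stop("lambda must be finite and >= 0", call. = FALSE)
  }
  if (lambda == 0) {
    w <- rep(1 / length(years), length(years))
  } else {
    z <- lambda * (years - min(years))
    z <- z - max(z)                      # overflow guard for large lambda
    w <- exp(z) / sum(exp(z))
  }
  names(w) <- years
  attr(w, "lambda") <- lambda
  attr(w, "origin") <- min(years)
  w
}

#' Temporally weighted indicator profiles per country
#'
#' Computes, for each country, the exponentially weighted mean of each
#' indicator over the years where that indicator is observed; weights are
#' renormalized per indicator over its own non-missing years, so each
#' weighted mean is a convex combination of observed values. Countries
#' missing an entire indicator are excluded (listed in the `dropped`
#' attribute), never imputed.
#'
#' @param panel long indicator panel (`country, year, gdp_pc, growth,
#'   health_pc`).
#' @param lambda decay parameter, >= 0.
#' @return data.frame of class `flp_profiles` with columns `country`,
#'   `gdp_pc`, `health_pc`, `growth`, `n_years`, plus attributes `lambda`
#'   and `dropped`.
#' @export
weighted_profiles <- function(panel, lambda) {
  assert_columns(panel, c("country", "year", INDICATORS), "indicator panel")
  by_country <- split(panel, panel$country)
  rows <- lapply(by_country, function(d) {
    means <- vapply(c("gdp_pc", "health_pc", "growth"), function(ind) {
      ok <- !is.na(d[[ind]])
      if (!any(ok)) return(NA_real_)
      w <- temporal_weights(d$year[ok], lambda)
      vals <- d[[ind]][ok][order(d$year[ok])]
      sum(w * vals)
    }, numeric(1))
    data.frame(country = d$country[1], gdp_pc = means[["gdp_pc"]],
               health_pc = means[["health_pc"]], growth = means[["growth"]],
               n_years = length(unique(d$year)), stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  usable <- stats::complete.cases(prof[, c("gdp_pc", "health_pc", "growth")])
  dropped <- prof$country[!usable]
  prof <- prof[usable, , drop = FALSE]
  if (nrow(prof) == 0L) stop("no country has usable indicator data", call. = FALSE)
  rownames(prof) <- NULL
  attr(prof, "lambda") <- lambda
  attr(prof, "dropped") <- dropped
  class(prof) <- c("flp_profiles", class(prof))
  prof
}

profile_matrix <- function(profiles, standardize = TRUE) {
  x <- as.matrix(profiles[, c("gdp_pc", "health_pc", "growth")])
  rownames(x) <- profiles$country
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    x <- scale(x, center = ctr, scale = scl)
    attr(x, "scaled:center") <- ctr
    attr(x, "scaled:scale") <- scl
  }
  x
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = prob)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - matrix(x[idx, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

run_kmeans_restarts <- function(x, k, restarts, iter_max = 300L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    centers <- unique(centers)
    if (nrow(centers) < k) next
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) {
    stop("k-means failed on every restart (k may exceed the number of ",
         "distinct points)", call. = FALSE)
  }
  best
}

# order clusters by decreasing gdp_pc centroid (original units) and name
# them developed, developing, cluster_3, ...
cluster_names <- function(k) {
  if (k == 1L) return("cluster_1")
  c("developed", "developing",
    if (k > 2L) paste0("cluster_", 3:k))
}

#' K-means typology of countries from weighted indicator profiles
#'
#' Clusters countries on their temporally weighted indicator profiles with
#' restarted k-means (k-means++ seeding, Lloyd iterations, best of
#' `restarts` by within-cluster sum of squares). Indicators are
#' z-standardized across countries by default, so the USD-scale indicators
#' do not dominate the Euclidean metric. Clusters are labelled by their GDP
#' per capita centroid in original units: the richest cluster is
#' `"developed"`, the next `"developing"`, further clusters `"cluster_3"`,
#' and so on.
#'
#' @param profiles a [weighted_profiles()] data frame.
#' @param k number of clusters (2 <= k <= number of countries; k = 1 is
#'   allowed and returns the grand centroid).
#' @param restarts number of k-means++ restarts.
#' @param seed integer seed for the restarts (local to the call).
#' @param standardize z-standardize the three indicators first (default).
#' @return Object of class `flp_typology`: `labels` (named character
#'   vector), `centroids` (original units) and `centroids_std`
#'   (standardized units, `NULL` when `standardize = FALSE`), `wcss`,
#'   `silhouette` (mean width; `NA` for k = 1), `sizes`, `k`, `lambda`,
#'   `standardized`, and the per-country distances to each centroid.
#' @export
kmeans_fit <- function(profiles, k, restarts = 50L, seed = 1L,
                       standardize = TRUE) {
  x <- profile_matrix(profiles, standardize)
  n <- nrow(x)
  if (k > n) stop("k = ", k, " exceeds the number of countries (", n, ")",
                  call. = FALSE)
  if (k > nrow(unique(x))) {
    stop("k exceeds the number of distinct profiles", call. = FALSE)
  }
  km <- withr::with_seed(seed, run_kmeans_restarts(x, k, restarts))

  centers_std <- km$centers
  centers_orig <- if (standardize) {
    sweep(sweep(centers_std, 2, attr(x, "scaled:scale"), "*"), 2,
          attr(x, "scaled:center"), "+")
  } else centers_std
  ord <- order(centers_orig[, "gdp_pc"], decreasing = TRUE)
  nm <- cluster_names(k)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)            # original cluster id -> rank
  labels <- nm[relabel[km$cluster]]
  names(labels) <- rownames(x)
  centroids <- centers_orig[ord, , drop = FALSE]
  rownames(centroids) <- nm
  centroids_std <- centers_std[ord, , drop = FALSE]
  rownames(centroids_std) <- nm

  dist_to <- sapply(seq_len(k), function(j) {
    sqrt(rowSums((x - matrix(centers_std[ord[j], ], n, ncol(x),
                             byrow = TRUE))^2))
  })
  dist_to <- matrix(dist_to, nrow = n,
                    dimnames = list(rownames(x), nm))

  sil <- if (k >= 2L) silhouette_mean(x, labels) else NA_real_
  out <- list(labels = labels, centroids = centroids,
              centroids_std = if (standardize) centroids_std else NULL,
              wcss = km$tot.withinss, silhouette = sil,
              sizes = table(factor(labels, levels = nm)),
              k = k, lambda = attr(profiles, "lambda"),
              standardized = standardize, distances = dist_to)
  class(out) <- "flp_typology"
  out
}

#' @export
print.flp_typology <- function(x, ...) {
  cat(sprintf("K-means typology (k = %d, lambda = %s)\n", x$k,
              format(x$lambda %||% NA)))
  cat(sprintf("  WCSS %.4f, mean silhouette %s\n", x$wcss,
              ifelse(is.na(x$silhouette), "NA", sprintf("%.4f", x$silhouette))))
  print(x$sizes)
  invisible(x)
}

#' Mean silhouette width of a clustering
#'
#' Mean over points of `(b - a) / max(a, b)` where `a` is the mean distance
#' to the point's own cluster and `b` the smallest mean distance to another
#' cluster; points in singleton clusters score 0.
#'
#' @param points numeric matrix (rows = entities) or `dist` object.
#' @param labels cluster labels, one per point; at least two non-empty
#'   clusters required.
#' @return mean silhouette width (scalar).
#' @export
silhouette_mean <- function(points, labels) {
  d <- if (inherits(points, "dist")) points else stats::dist(points)
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2L) {
    stop("silhouette requires at least two clusters", call. = FALSE)
  }
  if (all(tabulate(cl) == 1L)) return(0)   # all-singleton clustering
  sil <- cluster::silhouette(cl, d)
  mean(sil[, "sil_width"])
}

#' Elbow curve: within-cluster sum of squares over k
#'
#' @param profiles a [weighted_profiles()] data frame.
#' @param k_range integer vector of cluster counts to evaluate.
#' @param restarts,seed,standardize as in [kmeans_fit()].
#' @return data.frame with columns `k`, `wcss` and `delta_wcss` (the drop
#'   from the previous k; `NA` for the first row). WCSS is non-increasing
#'   in k; an inversion triggers a warning and a re-run with more restarts.
#' @export
elbow_curve <- function(profiles, k_range = 1:6, restarts = 50L, seed = 1L,
                        standardize = TRUE) {
  k_range <- sort(unique(as.integer(k_range)))
  x <- profile_matrix(profiles, standardize)
  wcss <- vapply(k_range, function(k) {
    if (k == 1L) {
      sum(scale(x, scale = FALSE)^2)
    } else {
      kmeans_fit(profiles, k, restarts, seed + k, standardize)$wcss
    }
  }, numeric(1))
  for (i in seq_along(wcss)[-1]) {
    if (wcss[i] > wcss[i - 1] + 1e-8) {
      warning("WCSS increased from k = ", k_range[i - 1], " to k = ",
              k_range[i], "; re-running with more restarts")
      wcss[i] <- kmeans_fit(profiles, k_range[i], restarts * 4L,
                            seed + 100L + k_range[i], standardize)$wcss
    }
  }
  data.frame(k = k_range, wcss = wcss, delta_wcss = c(NA, -diff(wcss)))
}

#' Sensitivity of the typology to the temporal decay parameter
#'
#' Re-weights, re-standardizes and re-clusters the panel for every value of
#' `lambda` in the grid. For each lambda it records the silhouette of the
#' two-cluster solution, the suggested optimal k (argmax mean silhouette
#' over `k_candidates`), group sizes at k = 2, and the agreement rate of
#' the k = 2 labels with the reference lambda's labels (labels are aligned
#' across runs by the GDP-per-capita centroid ordering, so agreement is
#' well defined without permutation matching).
#'
#' @param panel long indicator panel.
#' @param lambda_grid numeric grid of decay values (default 0 to 0.5 by
#'   0.05).
#' @param reference_lambda the grid value agreement is measured against.
#' @param k_candidates cluster counts searched for the suggested k.
#' @param restarts,seed,standardize as in [kmeans_fit()].
#' @return Object of class `flp_sensitivity`: `grid` (one row per lambda
#'   with `lambda, silhouette_k2, suggested_k, silhouette_suggested,
#'   n_developed, n_developing, agreement, n_changed`), `labels_k2` (matrix
#'   country x lambda), `changes` (list per lambda of data frames
#'   `country, from, to`), `reference_lambda`, and the k = 2 fits.
#' @export
sensitivity_analysis <- function(panel, lambda_grid = seq(0, 0.5, by = 0.05),
                                 reference_lambda = 0.2, k_candidates = 2:6,
                                 restarts = 50L, seed = 1L,
                                 standardize = TRUE) {
  if (length(lambda_grid) == 0L) stop("empty lambda grid", call. = FALSE)
  ref_idx <- which(abs(lambda_grid - reference_lambda) < 1e-12)
  if (length(ref_idx) != 1L) {
    stop("reference_lambda must appear exactly once in lambda_grid",
         call. = FALSE)
  }
  fits_k2 <- list()
  rows <- list()
  for (i in seq_along(lambda_grid)) {
    lam <- lambda_grid[i]
    prof <- weighted_profiles(panel, lam)
    fits_by_k <- lapply(k_candidates, function(k) {
      kmeans_fit(prof, k, restarts, derive_seed(seed, i * 100L + k),
                 standardize)
    })
    sil_by_k <- vapply(fits_by_k, `[[`, numeric(1), "silhouette")
    suggested <- k_candidates[which.max(sil_by_k)]
    fit2 <- if (2L %in% k_candidates) {
      fits_by_k[[match(2L, k_candidates)]]
    } else {
      kmeans_fit(prof, 2L, restarts, derive_seed(seed, i * 100L + 2L),
                 standardize)
    }
    fits_k2[[i]] <- fit2
    rows[[i]] <- data.frame(
      lambda = lam,
      silhouette_k2 = fit2$silhouette,
      suggested_k = suggested,
      silhouette_suggested = max(sil_by_k),
      n_developed = as.integer(fit2$sizes["developed"]),
      n_developing = as.integer(fit2$sizes["developing"]))
  }
  grid <- do.call(rbind, rows)

  countries <- Reduce(intersect, lapply(fits_k2, function(f) names(f$labels)))
  labels_k2 <- vapply(fits_k2, function(f) f$labels[countries],
                      character(length(countries)))
  labels_k2 <- matrix(labels_k2, nrow = length(countries),
                      dimnames = list(countries, format(lambda_grid)))
  ref_labels <- labels_k2[, ref_idx]
  changes <- lapply(seq_along(lambda_grid), function(i) {
    diff <- labels_k2[, i] != ref_labels
    data.frame(country = countries[diff], from = ref_labels[diff],
               to = labels_k2[diff, i], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  grid$agreement <- vapply(seq_along(lambda_grid), function(i) {
    mean(labels_k2[, i] == ref_labels)
  }, numeric(1))
  grid$n_changed <- vapply(changes, nrow, integer(1))

  out <- list(grid = grid, labels_k2 = labels_k2, changes = changes,
              reference_lambda = reference_lambda, fits_k2 = fits_k2,
              lambda_grid = lambda_grid)
  class(out) <- "flp_sensitivity"
  out
}

#' @export
print.flp_sensitivity <- function(x, ...) {
  cat("Temporal-weighting sensitivity analysis (reference lambda =",
      x$reference_lambda, ")\n")
  print(x$grid, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Choose the decay parameter under a cluster-count constraint
#'
#' Among grid rows whose suggested optimal k equals the constraint, returns
#' the lambda with the highest silhouette at that k; exact ties break
#' toward the smaller lambda. Stable under reordering of the grid.
#'
#' @param sens an [sensitivity_analysis()] result (or its `grid`).
#' @param k the required cluster count (default 2).
#' @return the chosen lambda (scalar).
#' @export
select_configuration <- function(sens, k = 2L) {
  grid <- if (inherits(sens, "flp_sensitivity")) sens$grid else sens
  cand <- grid[grid$suggested_k == k, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no lambda in the grid suggests k = ", k, call. = FALSE)
  }
  sil <- cand$silhouette_suggested
  best <- which(sil >= max(sil) - 1e-12)
  min(cand$lambda[best])
}

#' Narrative table for countries whose label flips across the grid
#'
#' For each country whose two-cluster label varies across the lambda grid,
#' reports its label at every lambda, the lambda values where it differs
#' from the reference, the direction of change, and its indicator profile
#' at the reference lambda next to both reference centroids.
#'
#' @param sens an [sensitivity_analysis()] result.
#' @param panel the indicator panel the analysis ran on (used to recompute
#'   reference-lambda profiles for the changers).
#' @return data.frame with one row per changer (zero rows when the grid is
#'   fully stable): `country`, `changed_at` (comma-separated lambdas),
#'   `direction`, reference-lambda indicator values, and the distance to
#'   each reference centroid.
#' @export
borderline_report <- function(sens, panel) {
  stopifnot(inherits(sens, "flp_sensitivity"))
  ref_idx <- which(abs(sens$lambda_grid - sens$reference_lambda) < 1e-12)
  ref_fit <- sens$fits_k2[[ref_idx]]
  changers <- sort(unique(unlist(lapply(sens$changes, function(d) d$country))))
  if (length(changers) == 0L) {
    return(data.frame(country = character(0), changed_at = character(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  prof <- weighted_profiles(panel, sens$reference_lambda)
  rows <- lapply(changers, function(ctry) {
    lab <- sens$labels_k2[ctry, ]
    ref_lab <- lab[ref_idx]
    flip <- which(lab != ref_lab)
    dirs <- unique(paste(ref_lab, "->", lab[flip]))
    p <- prof[prof$country == ctry, , drop = FALSE]
    data.frame(country = ctry,
               changed_at = paste(format(sens$lambda_grid[flip], trim = TRUE),
                                  collapse = ", "),
               direction = paste(dirs, collapse = "; "),
               reference_label = unname(ref_lab),
               gdp_pc = p$gdp_pc, health_pc = p$health_pc, growth = p$growth,
               dist_developed = unname(ref_fit$distances[ctry, "developed"]),
               dist_developing = unname(ref_fit$distances[ctry, "developing"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
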