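# Seeded generators for indicator panels and FLP records. These emulate the
# structure the analysis assumes: two latent development groups with strongly
# contrasting indicator centroids, irregular year coverage per country, a
# country-level random intercept in food-loss percentages, and structural
# (early-year-biased) missingness in commodity/activity/FLP fields.

COMMODITY_GROUPS <- c("grains", "roots and tubers", "vegetables", "fruits",
                      "pulses", "meat products", "dairy and eggs", "oilseeds",
                      "sugar products", "beverages", "others")

ACTIVITY_GROUPS <- c("harvest and on-farm operations", "processing",
                     "transport and distribution", "storage",
                     "marketing and retail", "consumption", "packaging",
                     "others")

# raw source labels emitted by the generator; the shipped synthetic category
# map sends each back to its group
RAW_COMMODITY_LABELS <- list(
  "grains" = c("wheat", "maize", "rice", "barley"),
  "roots and tubers" = c("potatoes", "cassava", "yams"),
  "vegetables" = c("tomatoes", "onions", "cabbages"),
  "fruits" = c("bananas", "apples", "oranges"),
  "pulses" = c("beans", "lentils", "chickpeas"),
  "meat products" = c("poultry meat", "bovine meat", "pig meat"),
  "dairy and eggs" = c("milk", "eggs", "cheese"),
  "oilseeds" = c("soybeans", "sunflower seed", "rapeseed"),
  "sugar products" = c("sugar cane", "sugar beet"),
  "beverages" = c("coffee", "tea", "cocoa beans"),
  "others" = c("spices", "honey"))

RAW_ACTIVITY_LABELS <- list(
  "harvest and on-farm operations" = c("harvesting", "threshing", "on-farm handling"),
  "processing" = c("milling", "processing", "canning"),
  "transport and distribution" = c("transport", "distribution", "loading"),
  "storage" = c("storage", "warehousing"),
  "marketing and retail" = c("retail", "wholesale", "marketing"),
  "consumption" = c("household consumption", "food service"),
  "packaging" = c("packaging", "packing"),
  "others" = c("unspecified", "whole supply chain"))

#' Configuration for the synthetic indicator-panel generator
#'
#' Defines two latent development groups of countries. Each country draws a
#' country-level mean per indicator around its group centroid (so a
#' random-intercept structure exists in the indicators themselves), then
#' year-level values with noise and optional linear drift; only a random
#' fraction of the study years is observed per country, emulating irregular
#' panel coverage.
#'
#' Default centroids are the cluster means of a typical global
#' developed/developing contrast: 13 "developed" countries around GDP per
#' capita USD 55,005, health expenditure per capita USD 5,540 and growth
#' 1.58%, and 92 "developing" countries around USD 4,869 / USD 259 / 3.19%.
#' Within-group spreads are synthetic choices set for clean separability
#' (roughly ten within-group SDs between the group centroids).
#'
#' @param n_developed,n_developing country counts per latent group.
#' @param centroids 2x3 numeric matrix (rows `developed`, `developing`;
#'   columns `gdp_pc`, `health_pc`, `growth`) of group centroids.
#' @param country_sd 2x3 matrix of between-country SDs around the centroid.
#' @param year_sd 2x3 matrix of within-country year-to-year noise SDs.
#' @param years integer vector of study years.
#' @param coverage_range length-2 vector; each country's fraction of years
#'   observed is drawn uniformly from this interval (values in (0, 1]).
#' @param drift 2x3 matrix of per-year linear drift added to each indicator
#'   (default zero).
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return A validated list of class `indicator_sim_config`.
#' @export
indicator_sim_config <- function(n_developed = 13L, n_developing = 92L,
                                 centroids = default_indicator_centroids(),
                                 country_sd = default_indicator_country_sd(),
                                 year_sd = default_indicator_year_sd(),
                                 years = 2000:2022,
                                 coverage_range = c(0.5, 1),
                                 drift = matrix(0, 2, 3,
                                                dimnames = dimnames(centroids)),
                                 seed = 1L) {
  stopifnot(n_developed >= 1L, n_developing >= 1L,
            all(dim(centroids) == c(2L, 3L)),
            all(dim(country_sd) == c(2L, 3L)), all(country_sd >= 0),
            all(dim(year_sd) == c(2L, 3L)), all(year_sd >= 0),
            length(years) >= 1L,
            length(coverage_range) == 2L,
            coverage_range[1] > 0, coverage_range[2] <= 1,
            coverage_range[1] <= coverage_range[2])
  cfg <- list(n_developed = as.integer(n_developed),
              n_developing = as.integer(n_developing),
              centroids = centroids, country_sd = country_sd,
              year_sd = year_sd, years = as.integer(years),
              coverage_range = coverage_range, drift = drift,
              seed = as.integer(seed))
  class(cfg) <- "indicator_sim_config"
  cfg
}

sim_matrix <- function(developed, developing) {
  m <- rbind(developed = developed, developing = developing)
  colnames(m) <- c("gdp_pc", "health_pc", "growth")
  m
}

#' @rdname indicator_sim_config
#' @export
default_indicator_centroids <- function() {
  sim_matrix(c(55005, 5540, 1.58), c(4869, 259, 3.19))
}

#' @rdname indicator_sim_config
#' @export
default_indicator_country_sd <- function() {
  sim_matrix(c(8000, 900, 1.0), c(1500, 80, 1.2))
}

#' @rdname indicator_sim_config
#' @export
default_indicator_year_sd <- function() {
  sim_matrix(c(2000, 250, 1.2), c(600, 40, 1.5))
}

#' Generate a synthetic country-year indicator panel
#'
#' @param cfg an [indicator_sim_config()].
#' @return A list of class `flp_sim_panel` with `panel` (long indicator
#'   panel), `labels` (named character vector of true groups per country),
#'   `country_means` (the latent country-level indicator means) and
#'   `config`. GDP and health expenditure are floored at zero (rare under
#'   the defaults); the floor count is in `n_floored`.
#' @export
generate_indicator_panel <- function(cfg) {
  stopifnot(inherits(cfg, "indicator_sim_config"))
  n <- cfg$n_developed + cfg$n_developing
  if (n < 1L) stop("config generates zero countries", call. = FALSE)
  withr::with_seed(cfg$seed, {
    countries <- sprintf("Country%03d", seq_len(n))
    groups <- sample(rep(c("developed", "developing"),
                         c(cfg$n_developed, cfg$n_developing)))
    names(groups) <- countries
    means <- matrix(NA_real_, n, 3,
                    dimnames = list(countries, colnames(cfg$centroids)))
    rows <- vector("list", n)
    n_floored <- 0L
    for (i in seq_len(n)) {
      g <- groups[i]
      mu <- cfg$centroids[g, ] + stats::rnorm(3, 0, cfg$country_sd[g, ])
      means[i, ] <- mu
      cov_frac <- stats::runif(1, cfg$coverage_range[1], cfg$coverage_range[2])
      n_obs <- max(1L, round(cov_frac * length(cfg$years)))
      obs_years <- sort(sample(cfg$years, n_obs))
      vals <- sapply(seq_len(3), function(j) {
        mu[j] + cfg$drift[g, j] * (obs_years - min(cfg$years)) +
          stats::rnorm(length(obs_years), 0, cfg$year_sd[g, j])
      })
      vals <- matrix(vals, ncol = 3)
      for (j in c(1L, 2L)) {             # gdp_pc, health_pc are non-negative
        neg <- vals[, j] < 0
        n_floored <- n_floored + sum(neg)
        vals[neg, j] <- 0
      }
      rows[[i]] <- data.frame(country = countries[i], year = obs_years,
                              gdp_pc = vals[, 1], health_pc = vals[, 2],
                              growth = vals[, 3], stringsAsFactors = FALSE)
    }
    panel <- do.call(rbind, rows)[, c("country", "year", INDICATORS)]
    rownames(panel) <- NULL
    out <- list(panel = panel, labels = groups, country_means = means,
                n_floored = n_floored, config = cfg)
    class(out) <- "flp_sim_panel"
    out
  })
}

#' Default generative coefficients for synthetic food-loss strata
#'
#' One row per stratum with intercept `beta0` (mean FLP in developed
#' countries at year 2000), `beta1` (shift for developing countries),
#' `beta2` (per-year linear trend) and `coverage` (fraction of countries
#' reporting the stratum at all; `beverages` is near-empty by default so
#' that coverage-based screening has a realistic casualty). Magnitudes are
#' on the FLP percentage scale and chosen so that, with the default noise
#' SDs, essentially no observation needs clipping at 0 or 100.
#'
#' @param type `"commodity"` or `"activity"`.
#' @return data.frame with columns `stratum, beta0, beta1, beta2, coverage`.
#' @export
default_flp_betas <- function(type = c("commodity", "activity")) {
  type <- match.arg(type)
  if (type == "commodity") {
    data.frame(
      stratum = COMMODITY_GROUPS,
      beta0 = c(18, 16, 14, 12, 17, 12, 16, 24, 12, 18, 14),
      beta1 = c(-6, 2, 2, 3.5, -5, 1, 2.5, -10, 3, -6, 0.5),
      beta2 = c(0.05, -0.1, 0.05, 0.05, 0.05, 0.1, -0.1, 0.25, 0.2, 0, 0),
      coverage = c(rep(1, 9), 0.03, 1),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      stratum = ACTIVITY_GROUPS,
      beta0 = c(13, 16, 12, 14, 12, 22, 13, 14),
      beta1 = c(-1.5, -5.5, 1.5, -2, -1, -9, -1.6, -3),
      beta2 = c(0, 0.05, 0.05, -0.05, 0.15, 0.1, 0.09, -0.03),
      coverage = 1,
      stringsAsFactors = FALSE)
  }
}

#' Configuration for the synthetic food-loss-record generator
#'
#' Records are generated from a random-intercept linear model on the FLP
#' percentage scale: for country c, stratum g and year t,
#' `flp = beta0_g + beta1_g * D_c + beta2_g * (t - 2000) + u_c + e`,
#' with `D_c = 1` for developing countries, `u_c ~ N(0, sigma_u^2)` drawn
#' once per country and shared across strata, and `e ~ N(0, sigma_e^2)` per
#' observation. Values are clipped to \[0, 100\] and the clip count
#' reported. Structural missingness is applied to the commodity, activity
#' and FLP fields with probabilities that ramp up in earlier years
#' (logistic ramp), mimicking reporting gaps concentrated in the early part
#' of the study window.
#'
#' @param betas coefficient table as from [default_flp_betas()]; must have
#'   one row per stratum to generate.
#' @param strata_type `"commodity"` or `"activity"`: which grouping drives
#'   the generative coefficients. The other field's raw label is assigned
#'   uniformly at random from its vocabulary.
#' @param sigma_u country random-intercept SD (FLP percentage points).
#' @param sigma_e residual SD (FLP percentage points).
#' @param obs_per_cell observations generated per (country, stratum) cell.
#' @param years candidate observation years.
#' @param miss_commodity,miss_activity,miss_flp overall missingness rates
#'   for the three fields (each in \[0, 1)).
#' @param ramp_midpoint,ramp_scale logistic ramp of missingness over years:
#'   field-level probabilities are proportional to
#'   `plogis((ramp_midpoint - year) / ramp_scale)`, rescaled so the overall
#'   rate matches the configured one.
#' @param seed integer seed.
#' @return A validated list of class `flp_sim_config`.
#' @export
flp_sim_config <- function(betas = default_flp_betas("commodity"),
                           strata_type = c("commodity", "activity"),
                           sigma_u = 3, sigma_e = 4, obs_per_cell = 3L,
                           years = 2000:2022,
                           miss_commodity = 0.144, miss_activity = 0.24,
                           miss_flp = 0.144,
                           ramp_midpoint = 2008, ramp_scale = 4,
                           seed = 1L) {
  strata_type <- match.arg(strata_type)
  assert_columns(betas, c("stratum", "beta0", "beta1", "beta2"),
                 "beta table")
  if (!"coverage" %in% names(betas)) betas$coverage <- 1
  if (anyNA(betas[c("beta0", "beta1", "beta2")])) {
    stop("every stratum needs beta0, beta1 and beta2", call. = FALSE)
  }
  stopifnot(sigma_u >= 0, sigma_e >= 0, obs_per_cell >= 1L,
            miss_commodity >= 0, miss_commodity < 1,
            miss_activity >= 0, miss_activity < 1,
            miss_flp >= 0, miss_flp < 1)
  cfg <- list(betas = betas, strata_type = strata_type,
              sigma_u = sigma_u, sigma_e = sigma_e,
              obs_per_cell = as.integer(obs_per_cell),
              years = as.integer(years),
              miss = c(commodity = miss_commodity, activity = miss_activity,
                       flp = miss_flp),
              ramp_midpoint = ramp_midpoint, ramp_scale = ramp_scale,
              seed = as.integer(seed))
  class(cfg) <- "flp_sim_config"
  cfg
}

# year-ramped missingness: probability per record, overall mean == rate
ramp_probabilities <- function(years, rate, midpoint, scale) {
  if (rate == 0) return(rep(0, length(years)))
  v <- stats::plogis((midpoint - years) / scale)
  p <- rate * v / mean(v)
  pmin(p, 0.97)
}

raw_label_for <- function(group, vocab) {
  labels <- vocab[[group]]
  if (is.null(labels)) group else labels[sample.int(length(labels), 1L)]
}

#' Generate synthetic food-loss records from a random-intercept model
#'
#' @param cfg an [flp_sim_config()].
#' @param labels named character vector mapping every country to
#'   `"developed"` or `"developing"` (e.g. the `labels` element of
#'   [generate_indicator_panel()] output).
#' @return A list of class `flp_sim_records` with `records` (standard FLP
#'   record data frame, raw labels filled, group columns `NA` until
#'   [categorize()] runs), and `truth`: the generating coefficient table,
#'   `sigma_u`, `sigma_e`, per-country intercepts `u`, `n_clipped`, and the
#'   per-field missingness actually applied.
#' @export
generate_flp_panel <- function(cfg, labels) {
  stopifnot(inherits(cfg, "flp_sim_config"))
  if (is.null(names(labels)) || !all(labels %in% c("developed", "developing"))) {
    stop("labels must be a named vector of 'developed'/'developing'",
         call. = FALSE)
  }
  countries <- names(labels)
  withr::with_seed(cfg$seed, {
    u <- stats::rnorm(length(countries), 0, cfg$sigma_u)
    names(u) <- countries
    rows <- list()
    for (s in seq_len(nrow(cfg$betas))) {
      b <- cfg$betas[s, ]
      reporting <- countries[stats::runif(length(countries)) <= b$coverage]
      for (ctry in reporting) {
        n_obs <- cfg$obs_per_cell
        yrs <- if (n_obs <= length(cfg$years)) {
          sort(sample(cfg$years, n_obs))
        } else sort(sample(cfg$years, n_obs, replace = TRUE))
        d <- as.numeric(labels[ctry] == "developing")
        mu <- b$beta0 + b$beta1 * d + b$beta2 * (yrs - 2000)
        flp <- mu + u[ctry] + stats::rnorm(n_obs, 0, cfg$sigma_e)
        if (cfg$strata_type == "commodity") {
          com <- vapply(seq_len(n_obs), function(i)
            raw_label_for(b$stratum, RAW_COMMODITY_LABELS), character(1))
          act_group <- sample(ACTIVITY_GROUPS, n_obs, replace = TRUE)
          act <- vapply(act_group, raw_label_for, character(1),
                        vocab = RAW_ACTIVITY_LABELS)
        } else {
          act <- vapply(seq_len(n_obs), function(i)
            raw_label_for(b$stratum, RAW_ACTIVITY_LABELS), character(1))
          com_group <- sample(setdiff(COMMODITY_GROUPS, "beverages"), n_obs,
                              replace = TRUE)
          com <- vapply(com_group, raw_label_for, character(1),
                        vocab = RAW_COMMODITY_LABELS)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          country = ctry, year = yrs, commodity_raw = com,
          activity_raw = act, flp = flp,
          commodity_group = NA_character_, activity_group = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    rec <- do.call(rbind, rows)
    rownames(rec) <- NULL
    n_clipped <- sum(rec$flp < 0 | rec$flp > 100)
    rec$flp <- pmin(pmax(rec$flp, 0), 100)
    applied <- c(commodity = 0, activity = 0, flp = 0)
    for (field in c("commodity", "activity", "flp")) {
      p <- ramp_probabilities(rec$year, cfg$miss[[field]],
                              cfg$ramp_midpoint, cfg$ramp_scale)
      hit <- stats::runif(nrow(rec)) < p
      col <- switch(field, commodity = "commodity_raw",
                    activity = "activity_raw", flp = "flp")
      rec[[col]][hit] <- NA
      applied[[field]] <- mean(hit)
    }
    out <- list(records = rec,
                truth = list(betas = cfg$betas, sigma_u = cfg$sigma_u,
                             sigma_e = cfg$sigma_e, u = u,
                             n_clipped = n_clipped,
                             missingness_applied = applied),
                config = cfg)
    class(out) <- "flp_sim_records"
    out
  })
}
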