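# Descriptive surfaces: mean FLP per stratum and development group, per-group
# linear time trends with SE, and coverage profiles for borderline countries.

#' Mean FLP by stratum and development group
#'
#' Cross-sectional averages of the food-loss percentage per (stratum,
#' development group) cell, aggregated over all available years. Borderline
#' countries, when named, are pulled out of their development group and
#' reported as their own columns. The default aggregation is over
#' observations; `level = "country"` averages country means instead (the
#' two differ when countries contribute unequal record counts).
#'
#' @param records screened FLP records with group columns filled.
#' @param labels named vector country -> `"developed"`/`"developing"`.
#' @param by `"commodity"` or `"activity"`.
#' @param level `"observation"` (default) or `"country"`.
#' @param borderline character vector of countries reported separately.
#' @return data.frame with one row per (stratum, group) cell: `stratum`,
#'   `group`, `mean_flp`, `n`, `year_min`, `year_max`.
#' @export
group_means <- function(records, labels, by = c("commodity", "activity"),
                        level = c("observation", "country"),
                        borderline = character(0)) {
  by <- match.arg(by)
  level <- match.arg(level)
  col <- paste0(by, "_group")
  assert_columns(records, c("country", "year", "flp", col), "records")
  rec <- records[!is.na(records[[col]]) & !is.na(records$flp), , drop = FALSE]
  rec$group <- ifelse(rec$country %in% borderline, rec$country,
                      unname(labels[rec$country]))
  if (anyNA(rec$group)) {
    stop("no development label for: ",
         paste(sort(unique(rec$country[is.na(rec$group)])), collapse = ", "),
         call. = FALSE)
  }
  cells <- split(rec, list(rec[[col]], rec$group), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(d) {
    m <- if (level == "observation") {
      mean(d$flp)
    } else {
      mean(tapply(d$flp, d$country, mean))
    }
    data.frame(stratum = d[[col]][1], group = d$group[1], mean_flp = m,
               n = nrow(d), year_min = min(d$year), year_max = max(d$year),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$stratum, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Linear time trend of FLP for one set of records
#'
#' Ordinary least squares of FLP on centered year for the records supplied
#' (typically one stratum crossed with one development group). Needs at
#' least three distinct years; otherwise an "insufficient years" flag is
#' returned instead of a slope.
#'
#' @param records FLP records (rows already restricted to the cell of
#'   interest); missing FLP values are dropped.
#' @param center centering constant for year (default 2000).
#' @return one-row data.frame: `slope`, `se`, `p`, `n`, `n_years`,
#'   `year_min`, `year_max`, `sufficient` (logical).
#' @export
trend_ols <- function(records, center = 2000) {
  assert_columns(records, c("year", "flp"), "records")
  d <- records[!is.na(records$flp) & !is.na(records$year), , drop = FALSE]
  n_years <- length(unique(d$year))
  if (n_years < 3L) {
    return(data.frame(slope = NA_real_, se = NA_real_, p = NA_real_,
                      n = nrow(d), n_years = n_years,
                      year_min = if (nrow(d)) min(d$year) else NA_integer_,
                      year_max = if (nrow(d)) max(d$year) else NA_integer_,
                      sufficient = FALSE))
  }
  fit <- stats::lm(flp ~ I(year - center), data = d)
  # summary warns on an exactly collinear ("perfect") fit; that case is
  # well defined here (slope exact, SE zero)
  sm <- suppressWarnings(summary(fit))$coefficients
  # a perfect linear fit has zero residual variance: slope exact, SE 0
  slope <- unname(sm[2, 1])
  se <- unname(sm[2, 2])
  p <- unname(sm[2, 4])
  if (!is.nan(se) && se < 1e-12) p <- 0
  data.frame(slope = slope, se = se, p = p, n = nrow(d), n_years = n_years,
             year_min = min(d$year), year_max = max(d$year),
             sufficient = TRUE)
}

#' Trend table: one OLS trend per stratum and development group
#'
#' @inheritParams group_means
#' @param center centering constant for year.
#' @return data.frame with one row per (stratum, group) cell and the
#'   [trend_ols()] columns.
#' @export
trend_table <- function(records, labels, by = c("commodity", "activity"),
                        borderline = character(0), center = 2000) {
  by <- match.arg(by)
  col <- paste0(by, "_group")
  rec <- records[!is.na(records[[col]]) & !is.na(records$flp), , drop = FALSE]
  rec$group <- ifelse(rec$country %in% borderline, rec$country,
                      unname(labels[rec$country]))
  cells <- split(rec, list(rec[[col]], rec$group), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(d) {
    cbind(data.frame(stratum = d[[col]][1], group = d$group[1],
                     stringsAsFactors = FALSE),
          trend_ols(d, center))
  }))
  out <- out[order(out$stratum, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Descriptive profiles for borderline countries
#'
#' For each named country: record count, year coverage (span and fraction
#' of the study window observed), and mean FLP per stratum. Countries
#' absent from the data get an empty row with a warning.
#'
#' @param records FLP records.
#' @param countries character vector of country names.
#' @param by `"commodity"` or `"activity"`.
#' @param window integer vector of study years used for the coverage
#'   fraction (default 2000:2022).
#' @return list with `summary` (one row per country: `n`, `year_min`,
#'   `year_max`, `n_years`, `coverage_fraction`) and `stratum_means` (long
#'   data.frame country x stratum).
#' @export
borderline_profiles <- function(records, countries,
                                by = c("commodity", "activity"),
                                window = 2000:2022) {
  by <- match.arg(by)
  col <- paste0(by, "_group")
  rows <- lapply(countries, function(ctry) {
    d <- records[records$country == ctry & !is.na(records$flp), , drop = FALSE]
    if (nrow(d) == 0L) {
      warning("no records for country: ", ctry)
      return(data.frame(country = ctry, n = 0L, year_min = NA_integer_,
                        year_max = NA_integer_, n_years = 0L,
                        coverage_fraction = 0, stringsAsFactors = FALSE))
    }
    data.frame(country = ctry, n = nrow(d), year_min = min(d$year),
               year_max = max(d$year), n_years = length(unique(d$year)),
               coverage_fraction = length(intersect(unique(d$year), window)) /
                 length(window),
               stringsAsFactors = FALSE)
  })
  means <- lapply(countries, function(ctry) {
    d <- records[records$country == ctry & !is.na(records$flp) &
                   !is.na(records[[col]]), , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    m <- tapply(d$flp, d[[col]], mean)
    data.frame(country = ctry, stratum = names(m), mean_flp = as.numeric(m),
               stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows),
       stratum_means = do.call(rbind, means))
}
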