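# Missing-data audit, categorization into analysis groups, and the
# coverage-based exclusion rules that define the analyzable sample.

#' Read a raw-label to analysis-group category map
#'
#' @param path two-column CSV with columns `raw`, `group`.
#' @param type `"commodity"` (11 target groups) or `"activity"` (8 groups);
#'   group labels outside the closed vocabulary are an error.
#' @return data.frame with columns `raw`, `group`.
#' @export
read_category_map <- function(path, type = c("commodity", "activity")) {
  type <- match.arg(type)
  map <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8")
  assert_columns(map, c("raw", "group"), "category map")
  if (anyDuplicated(map$raw)) {
    stop("category map assigns a raw label to more than one group: ",
         paste(unique(map$raw[duplicated(map$raw)]), collapse = ", "),
         call. = FALSE)
  }
  vocab <- if (type == "commodity") COMMODITY_GROUPS else ACTIVITY_GROUPS
  bad <- setdiff(unique(map$group), vocab)
  if (length(bad) > 0L) {
    stop("category map uses group label(s) outside the ", type,
         " vocabulary: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  map
}

#' Category maps shipped with the package
#'
#' Returns the default raw-to-group maps for the synthetic vocabulary
#' emitted by [generate_flp_panel()]. A separate, clearly incomplete stub
#' for FAO-style labels ships as
#' `system.file("extdata", "commodity_map_fao_stub.csv", package = "flptools")`;
#' real analyses are expected to supply their own audited map.
#'
#' @return list with elements `commodity` and `activity`, each a data.frame
#'   with columns `raw`, `group`.
#' @export
default_category_map <- function() {
  list(
    commodity = read_category_map(
      system.file("extdata", "commodity_map_synthetic.csv",
                  package = "flptools"), "commodity"),
    activity = read_category_map(
      system.file("extdata", "activity_map_synthetic.csv",
                  package = "flptools"), "activity"))
}

#' Assign commodity and activity groups to raw labels
#'
#' Every record is either grouped or listed as unmapped; no record is ever
#' dropped. Records whose raw label is missing, or absent from the map,
#' keep `NA` in the group column.
#'
#' @param records FLP record data frame.
#' @param map list with `commodity` and `activity` maps (see
#'   [default_category_map()]).
#' @return list of class `flp_categorized`: `records` (group columns
#'   filled), `unmapped` (list of unmatched raw commodity/activity labels),
#'   and `n_raw` (counts of distinct raw labels seen per field).
#' @export
categorize <- function(records, map = default_category_map()) {
  assert_columns(records, FLP_COLUMNS, "FLP records")
  rec <- records
  cm <- map$commodity
  am <- map$activity
  rec$commodity_group <- cm$group[match(rec$commodity_raw, cm$raw)]
  rec$activity_group <- am$group[match(rec$activity_raw, am$raw)]
  unmapped_com <- sort(unique(rec$commodity_raw[
    !is.na(rec$commodity_raw) & is.na(rec$commodity_group)]))
  unmapped_act <- sort(unique(rec$activity_raw[
    !is.na(rec$activity_raw) & is.na(rec$activity_group)]))
  out <- list(records = rec,
              unmapped = list(commodity = unmapped_com,
                              activity = unmapped_act),
              n_raw = c(commodity = length(unique(stats::na.omit(rec$commodity_raw))),
                        activity = length(unique(stats::na.omit(rec$activity_raw)))))
  class(out) <- "flp_categorized"
  out
}

#' Summarize missingness across key fields, years and countries
#'
#' @param records FLP record data frame (raw or categorized).
#' @return Object of class `flp_missingness`: total and analyzable record
#'   counts (analyzable = non-missing commodity label, activity label and
#'   FLP), per-field missing fractions, per-year and per-country coverage
#'   tables, and a commodity-group by activity-group count table when group
#'   columns are filled.
#' @export
missingness_report <- function(records) {
  assert_columns(records, c("country", "year", "commodity_raw",
                            "activity_raw", "flp"), "FLP records")
  n <- nrow(records)
  miss <- c(commodity = mean(is.na(records$commodity_raw)),
            activity = mean(is.na(records$activity_raw)),
            flp = mean(is.na(records$flp)))
  complete <- !is.na(records$commodity_raw) & !is.na(records$activity_raw) &
    !is.na(records$flp)
  per_year <- do.call(rbind, lapply(split(records, records$year), function(d) {
    data.frame(year = d$year[1], n = nrow(d),
               complete_share = mean(!is.na(d$commodity_raw) &
                                       !is.na(d$activity_raw) & !is.na(d$flp)))
  }))
  per_country <- do.call(rbind, lapply(split(records, records$country),
                                       function(d) {
    data.frame(country = d$country[1], n = nrow(d),
               n_years = length(unique(d$year)),
               complete_share = mean(!is.na(d$commodity_raw) &
                                       !is.na(d$activity_raw) & !is.na(d$flp)))
  }))
  rownames(per_year) <- rownames(per_country) <- NULL
  cross <- if (any(!is.na(records$commodity_group)) &&
               any(!is.na(records$activity_group))) {
    table(commodity = records$commodity_group,
          activity = records$activity_group, useNA = "no")
  } else NULL
  out <- list(total = n, analyzable = sum(complete),
              missing_fraction = miss, per_year = per_year,
              per_country = per_country, group_crosstab = cross)
  class(out) <- "flp_missingness"
  out
}

#' @export
print.flp_missingness <- function(x, ...) {
  cat("Missing-data report\n")
  cat(sprintf("  records            : %d (analyzable %d, %.1f%%)\n",
              x$total, x$analyzable, 100 * x$analyzable / x$total))
  cat(sprintf("  missing commodity  : %.1f%%\n", 100 * x$missing_fraction["commodity"]))
  cat(sprintf("  missing activity   : %.1f%%\n", 100 * x$missing_fraction["activity"]))
  cat(sprintf("  missing FLP        : %.1f%%\n", 100 * x$missing_fraction["flp"]))
  invisible(x)
}

#' Serialize a missingness report to JSON
#'
#' @param report an object from [missingness_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_missingness_report <- function(report, path) {
  stopifnot(inherits(report, "flp_missingness"))
  x <- report
  x$group_crosstab <- if (!is.null(x$group_crosstab)) {
    as.data.frame(x$group_crosstab, stringsAsFactors = FALSE)
  }
  class(x) <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Coverage thresholds defining an analyzable stratum
#'
#' A commodity or activity group must reach all three thresholds (counted on
#' records with non-missing FLP) to be retained for modelling. The defaults
#' (30 observations, 3 countries, 3 years) are deliberate, explicit
#' configuration: "insufficient coverage" must be an auditable rule, not a
#' judgement call.
#'
#' @param min_obs,min_countries,min_years integer thresholds, all >= 1.
#' @return list of class `flp_exclusion_rule`.
#' @export
exclusion_rule <- function(min_obs = 30L, min_countries = 3L, min_years = 3L) {
  stopifnot(min_obs >= 1L, min_countries >= 1L, min_years >= 1L)
  structure(list(min_obs = as.integer(min_obs),
                 min_countries = as.integer(min_countries),
                 min_years = as.integer(min_years)),
            class = "flp_exclusion_rule")
}

group_coverage <- function(records, col) {
  ok <- !is.na(records[[col]]) & !is.na(records$flp)
  d <- records[ok, , drop = FALSE]
  do.call(rbind, lapply(split(d, d[[col]]), function(g) {
    data.frame(group = g[[col]][1], n_obs = nrow(g),
               n_countries = length(unique(g$country)),
               n_years = length(unique(g$year)), stringsAsFactors = FALSE)
  }))
}

#' Apply coverage-based exclusions and listwise deletion
#'
#' First drops, wholesale, every commodity group and every activity group
#' that fails the coverage rule; then applies listwise deletion, removing
#' records missing `flp`, `commodity_group` or `activity_group` (the
#' modelling variables). Every dropped record is counted and retained +
#' excluded always reconciles with the input count.
#'
#' @param records categorized FLP record data frame.
#' @param rule an [exclusion_rule()].
#' @return list of class `flp_screened`: `records` (retained), `coverage`
#'   (per-group coverage tables), `excluded_groups` (list for commodity and
#'   activity), and `log` (data.frame of step, n_dropped, n_remaining).
#' @export
apply_exclusions <- function(records, rule = exclusion_rule()) {
  assert_columns(records, FLP_COLUMNS, "FLP records")
  stopifnot(inherits(rule, "flp_exclusion_rule"))
  n0 <- nrow(records)
  cov_com <- group_coverage(records, "commodity_group")
  cov_act <- group_coverage(records, "activity_group")
  fails <- function(cov) {
    if (is.null(cov)) return(character(0))
    cov$group[cov$n_obs < rule$min_obs |
                cov$n_countries < rule$min_countries |
                cov$n_years < rule$min_years]
  }
  excl_com <- fails(cov_com)
  excl_act <- fails(cov_act)

  log <- data.frame(step = character(0), n_dropped = integer(0),
                    n_remaining = integer(0), stringsAsFactors = FALSE)
  add_log <- function(log, step, before, after) {
    rbind(log, data.frame(step = step, n_dropped = before - after,
                          n_remaining = after, stringsAsFactors = FALSE))
  }
  rec <- records
  keep <- !(rec$commodity_group %in% excl_com)
  rec <- rec[keep, , drop = FALSE]
  log <- add_log(log, "commodity groups below coverage rule", n0, nrow(rec))
  n1 <- nrow(rec)
  keep <- !(rec$activity_group %in% excl_act)
  rec <- rec[keep, , drop = FALSE]
  log <- add_log(log, "activity groups below coverage rule", n1, nrow(rec))
  n2 <- nrow(rec)
  keep <- !is.na(rec$flp) & !is.na(rec$commodity_group) &
    !is.na(rec$activity_group)
  rec <- rec[keep, , drop = FALSE]
  log <- add_log(log, "listwise deletion (missing flp/commodity/activity)",
                 n2, nrow(rec))
  rownames(rec) <- NULL

  retained_com <- setdiff(unique(stats::na.omit(records$commodity_group)),
                          excl_com)
  if (length(retained_com) == 0L && length(excl_com) > 0L) {
    stop("the coverage rule excluded every commodity group", call. = FALSE)
  }
  out <- list(records = rec,
              coverage = list(commodity = cov_com, activity = cov_act),
              excluded_groups = list(commodity = sort(excl_com),
                                     activity = sort(excl_act)),
              rule = rule, log = log,
              n_input = n0, n_retained = nrow(rec),
              n_excluded = n0 - nrow(rec))
  class(out) <- "flp_screened"
  out
}

#' @export
print.flp_screened <- function(x, ...) {
  cat("Screening result\n")
  cat(sprintf("  input records    : %d\n", x$n_input))
  cat(sprintf("  retained         : %d\n", x$n_retained))
  cat(sprintf("  excluded         : %d\n", x$n_excluded))
  if (length(x$excluded_groups$commodity) > 0L)
    cat("  commodity groups dropped:",
        paste(x$excluded_groups$commodity, collapse = ", "), "\n")
  if (length(x$excluded_groups$activity) > 0L)
    cat("  activity groups dropped:",
        paste(x$excluded_groups$activity, collapse = ", "), "\n")
  invisible(x)
}
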