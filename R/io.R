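#' Read a country-year socioeconomic indicator panel
#'
#' Reads a CSV of GDP per capita (USD), GDP growth rate (%) and health
#' expenditure per capita (USD) into a long country-year panel. Two layouts
#' are supported: `"long"` (columns `country, year, gdp_pc, growth,
#' health_pc`, one row per country-year) and `"wide"` (columns `country,
#' indicator`, then one column per year, World-Bank style, with `indicator`
#' one of `gdp_pc`, `growth`, `health_pc`).
#'
#' Unparseable numeric cells (e.g. `"n/a"`, empty strings) become `NA`,
#' never zero. Duplicate (country, year) keys are a hard error.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param dialect `"long"` or `"wide"`.
#' @return A `data.frame` with columns `country` (character), `year`
#'   (integer), `gdp_pc`, `growth`, `health_pc` (numeric, `NA` where
#'   missing), one row per (country, year), with attributes `n_rows_read`
#'   and `n_missing_cells`.
#' @export
read_indicator_panel <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  panel <- switch(dialect,
    long = {
      assert_columns(raw, c("country", "year", INDICATORS), "long indicator CSV")
      data.frame(country = raw$country,
                 year = as.integer(parse_numeric(raw$year)),
                 gdp_pc = parse_numeric(raw$gdp_pc),
                 growth = parse_numeric(raw$growth),
                 health_pc = parse_numeric(raw$health_pc),
                 stringsAsFactors = FALSE)
    },
    wide = {
      assert_columns(raw, c("country", "indicator"), "wide indicator CSV")
      year_cols <- setdiff(names(raw), c("country", "indicator"))
      years <- as.integer(year_cols)
      if (anyNA(years)) {
        stop("wide dialect expects year column names; found: ",
             paste(year_cols[is.na(years)], collapse = ", "), call. = FALSE)
      }
      bad <- setdiff(unique(raw$indicator), INDICATORS)
      if (length(bad) > 0L) {
        stop("unknown indicator label(s) in wide CSV: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      long <- do.call(rbind, lapply(seq_along(year_cols), function(j) {
        data.frame(country = raw$country, indicator = raw$indicator,
                   year = years[j], value = parse_numeric(raw[[year_cols[j]]]),
                   stringsAsFactors = FALSE)
      }))
      out <- stats::reshape(long, idvar = c("country", "year"),
                            timevar = "indicator", direction = "wide")
      names(out) <- sub("^value\\.", "", names(out))
      for (ind in setdiff(INDICATORS, names(out))) out[[ind]] <- NA_real_
      rownames(out) <- NULL
      out[, c("country", "year", INDICATORS)]
    })

  key <- paste(panel$country, panel$year, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (country, year) keys: ",
         paste(gsub("\r", "/", dups), collapse = ", "), call. = FALSE)
  }
  panel <- panel[order(panel$country, panel$year), , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "n_rows_read") <- nrow(raw)
  attr(panel, "n_missing_cells") <- sum(is.na(panel[INDICATORS]))
  panel
}

#' Write an indicator panel to long-format CSV
#'
#' Inverse of [read_indicator_panel()] with `dialect = "long"`; the
#' write/read round trip is lossless for values and missingness.
#'
#' @param panel a long indicator panel data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_indicator_panel <- function(panel, path) {
  assert_columns(panel, c("country", "year", INDICATORS), "indicator panel")
  utils::write.csv(panel[, c("country", "year", INDICATORS)], path,
                   row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read long-format food-loss records
#'
#' Reads a CSV of food-loss observations (one row per country, year,
#' commodity, supply-chain activity) into the record layout used by the
#' screening and modelling modules. Raw commodity/activity labels are kept
#' verbatim for audit; group columns are only filled by [categorize()].
#'
#' @param path path to a UTF-8 CSV with columns `country`, `year`,
#'   `commodity_raw`, `activity_raw`, `flp` (optionally also
#'   `commodity_group`, `activity_group`).
#' @return A `data.frame` with the seven standard record columns; `flp`
#'   values outside \[0, 100\] are a hard error.
#' @export
read_flp_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  assert_columns(raw, c("country", "year", "commodity_raw", "activity_raw",
                        "flp"), "FLP CSV")
  rec <- data.frame(country = raw$country,
                    year = as.integer(parse_numeric(raw$year)),
                    commodity_raw = ifelse(trimws(raw$commodity_raw) == "",
                                           NA_character_, raw$commodity_raw),
                    activity_raw = ifelse(trimws(raw$activity_raw) == "",
                                          NA_character_, raw$activity_raw),
                    flp = parse_numeric(raw$flp),
                    stringsAsFactors = FALSE)
  rec$commodity_group <- if ("commodity_group" %in% names(raw)) {
    ifelse(trimws(raw$commodity_group) == "", NA_character_, raw$commodity_group)
  } else NA_character_
  rec$activity_group <- if ("activity_group" %in% names(raw)) {
    ifelse(trimws(raw$activity_group) == "", NA_character_, raw$activity_group)
  } else NA_character_
  bad <- which(!is.na(rec$flp) & (rec$flp < 0 | rec$flp > 100))
  if (length(bad) > 0L) {
    stop("flp outside [0, 100] on row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  rec
}

#' Write food-loss records to CSV
#'
#' @param records an FLP record data frame (see [read_flp_records()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flp_records <- function(records, path) {
  assert_columns(records, FLP_COLUMNS, "FLP records")
  utils::write.csv(records[, FLP_COLUMNS], path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a country-name harmonization table
#'
#' The table maps source spellings (e.g. `"Korea, Rep."`) to one canonical
#' display name per country, with a provenance tag recording which source
#' dialect each entry came from. The mapping must be functional: one
#' canonical name per source name.
#'
#' @param path CSV with columns `source_name`, `canonical_name` and
#'   optionally `provenance`.
#' @return A `data.frame` of class `flp_harmonization`.
#' @export
read_harmonization_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8")
  assert_columns(tab, c("source_name", "canonical_name"), "harmonization table")
  if (!"provenance" %in% names(tab)) tab$provenance <- "unspecified"
  if (anyDuplicated(tab$source_name)) {
    stop("harmonization table maps a source name more than once: ",
         paste(unique(tab$source_name[duplicated(tab$source_name)]),
               collapse = ", "), call. = FALSE)
  }
  class(tab) <- c("flp_harmonization", class(tab))
  tab
}

#' Harmonize country names against a lookup table
#'
#' Names found in the table are replaced by their canonical form; names
#' absent from the table pass through unchanged and are listed in the
#' `unmatched` report. Nothing is ever dropped silently, and harmonizing an
#' already-canonical list is the identity.
#'
#' @param names character vector of source country names.
#' @param table a harmonization table from [read_harmonization_table()]
#'   (or any data frame with `source_name`/`canonical_name` columns).
#' @return A list with `canonical` (character vector, same length and order
#'   as `names`) and `unmatched` (unique names not found in the table and
#'   not already canonical).
#' @export
harmonize_countries <- function(names, table) {
  assert_columns(table, c("source_name", "canonical_name"), "harmonization table")
  idx <- match(names, table$source_name)
  canonical <- ifelse(is.na(idx), names, table$canonical_name[idx])
  unmatched <- sort(unique(names[is.na(idx) &
                                   !(names %in% table$canonical_name)]))
  list(canonical = canonical, unmatched = unmatched)
}

#' Merge indicator panel and FLP records into a unified dataset
#'
#' Restricts both inputs to the set of countries present in each (the
#' "common-country" sample that defines the analysis), and records what was
#' dropped on either side. Inputs are assumed to be harmonized already.
#'
#' @param panel a long indicator panel.
#' @param records an FLP record data frame.
#' @return An object of class `flp_unified`: a list with elements `panel`,
#'   `records`, `countries` (sorted common countries), `n_common`, and
#'   `dropped` (list with `panel_only` and `flp_only` country names).
#' @export
build_unified_dataset <- function(panel, records) {
  assert_columns(panel, c("country", "year", INDICATORS), "indicator panel")
  assert_columns(records, c("country", "year", "flp"), "FLP records")
  pc <- unique(panel$country)
  fc <- unique(records$country)
  common <- sort(intersect(pc, fc))
  if (length(common) == 0L) {
    stop("no countries are common to the indicator panel and FLP records",
         call. = FALSE)
  }
  out <- list(panel = panel[panel$country %in% common, , drop = FALSE],
              records = records[records$country %in% common, , drop = FALSE],
              countries = common,
              n_common = length(common),
              dropped = list(panel_only = sort(setdiff(pc, common)),
                             flp_only = sort(setdiff(fc, common))))
  rownames(out$panel) <- rownames(out$records) <- NULL
  class(out) <- "flp_unified"
  out
}

#' @export
print.flp_unified <- function(x, ...) {
  cat("Unified food-loss dataset\n")
  cat(sprintf("  common countries : %d\n", x$n_common))
  cat(sprintf("  indicator rows   : %d\n", nrow(x$panel)))
  cat(sprintf("  FLP records      : %d\n", nrow(x$records)))
  cat(sprintf("  dropped (panel-only %d, FLP-only %d)\n",
              length(x$dropped$panel_only), length(x$dropped$flp_only)))
  invisible(x)
}

#' Export a unified dataset as one long CSV
#'
#' Joins the indicator panel onto each FLP record by (country, year) and
#' writes a single long CSV with columns `country, year, gdp_pc, growth,
#' health_pc, commodity_group, activity_group, flp`.
#'
#' @param unified an object from [build_unified_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_unified_dataset <- function(unified, path) {
  stopifnot(inherits(unified, "flp_unified"))
  rec <- unified$records
  pan <- unified$panel
  idx <- match(paste(rec$country, rec$year), paste(pan$country, pan$year))
  out <- data.frame(country = rec$country, year = rec$year,
                    gdp_pc = pan$gdp_pc[idx], growth = pan$growth[idx],
                    health_pc = pan$health_pc[idx],
                    commodity_group = rec$commodity_group,
                    activity_group = rec$activity_group,
                    flp = rec$flp, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}
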