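# internal helpers shared across modules

INDICATORS <- c("gdp_pc", "growth", "health_pc")

FLP_COLUMNS <- c("country", "year", "commodity_raw", "activity_raw", "flp",
                 "commodity_group", "activity_group")

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric coercion where unparseable cells ("n/a", "", "..") become NA, never 0
parse_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "n/a", "N/A", "na", "..", "-", ".")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# derive a stage seed from a master seed; double arithmetic stays exact
# below 2^53 and the result is kept under 2^31
derive_seed <- function(master, stage_index) {
  as.integer((as.numeric(master) * 1000003 +
                as.numeric(stage_index) * 7919) %% 2147483647)
}
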