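#' Read a country-year indicator panel from CSV
#'
#' One row per country-year; columns `country`, `date` (or
#' `assessment_date`), one column per configured indicator in its native
#' units, and optionally `population` and `people_in_need_millions`. Empty
#' cells are read as not available.
#'
#' @param path CSV path.
#' @param config The model configuration the panel must match.
#' @return A tibble ready for [score_panel()].
#' @export
read_panel <- function(path, config = default_model_config()) {
  config <- validate_model_config(config)
  if (!file.exists(path)) {
    rlang::abort(paste0("input panel not found: ", path),
                 class = "cescore_input_error")
  }
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("date" %in% names(panel) && !"assessment_date" %in% names(panel)) {
    names(panel)[names(panel) == "date"] <- "assessment_date"
  }
  required <- c("country", "assessment_date")
  miss <- setdiff(required, names(panel))
  if (length(miss) > 0L) {
    rlang::abort(paste0("input panel '", path, "' lacks column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "cescore_input_error")
  }
  known <- c(required, "population", "people_in_need_millions", config$name)
  extra <- setdiff(names(panel), known)
  if (length(extra) > 0L) {
    rlang::abort(paste0("unknown indicator column(s) in '", path, "': ",
                        paste(extra, collapse = ", ")),
                 class = "cescore_config_error")
  }
  panel$assessment_date <- as.character(panel$assessment_date)
  panel
}

#' Write a scored panel to CSV
#'
#' Rows are ordered by country and date, level weights are added alongside
#' the textual levels, and all score columns are formatted to two decimals so
#' that repeated runs produce byte-identical files.
#'
#' @param scored A tibble from [score_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scored_panel <- function(scored, path) {
  out <- scored[order(scored$country, scored$assessment_date), ]
  lev_cols <- grep("^level_", names(out), value = TRUE)
  for (lc in lev_cols) {
    wc <- sub("^level_", "weight_", lc)
    out[[wc]] <- fmt2(level_weight(out[[lc]]))
  }
  for (sc in c("vulnerability_sum", "exposure_sum", "severity_score",
               "need_score", "people_in_need_millions")) {
    if (sc %in% names(out)) out[[sc]] <- fmt2(out[[sc]])
  }
  # weights next to their levels, scores last
  tail_cols <- c("vulnerability_sum", "exposure_sum", "severity_score",
                 "need_score", "people_in_need_millions",
                 "imputed_indicators", "missing_indicators")
  ordered <- c("country", "assessment_date",
               as.vector(rbind(lev_cols, sub("^level_", "weight_", lev_cols))),
               intersect(tail_cols, names(out)))
  readr::write_csv(out[, ordered], path, na = "")
  invisible(path)
}

fmt2 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.2f", x))

#' Read an excess-mortality table from CSV
#'
#' Columns: `context` (a country-plus-period label) and
#' `excess_mortality_per_100k_year` (direct plus indirect deaths per 100,000
#' persons per year).
#'
#' @param path CSV path.
#' @return A tibble with the two columns, rates validated non-negative.
#' @export
read_mortality <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("mortality table not found: ", path),
                 class = "cescore_input_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("context", "excess_mortality_per_100k_year"), names(tab))
  if (length(miss) > 0L) {
    rlang::abort(paste0("mortality table '", path, "' lacks column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "cescore_input_error")
  }
  if (any(is.na(tab$excess_mortality_per_100k_year)) ||
      any(tab$excess_mortality_per_100k_year < 0)) {
    rlang::abort("excess mortality rates must be non-negative and present",
                 class = "cescore_input_error")
  }
  tab
}
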