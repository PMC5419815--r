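#' Classify a raw indicator value into a severity level
#'
#' Applies the indicator's two cut-offs. For a `higher_is_worse` indicator:
#' values below `cutoff_lo` are `low_medium`, values in `[cutoff_lo,
#' cutoff_hi)` are `high`, values at or above `cutoff_hi` are `extreme`. For
#' `lower_is_worse` indicators the comparisons are mirrored. A value exactly
#' at a cut-off is assigned the more severe level in both directions. `NA`
#' values (not available) propagate to `NA` levels.
#'
#' @param value Numeric vector of raw values in the indicator's native units;
#'   `NA` marks "not available".
#' @param definition A one-row indicator definition (see
#'   [indicator_definition()]).
#' @return Character vector of levels (`"low_medium"`, `"high"`,
#'   `"extreme"`), `NA` where the value is missing.
#' @examples
#' def <- indicator_definition("child_underweight", "vulnerability",
#'                             "higher_is_worse", 20, 30)
#' classify_indicator(c(5, 20, 30, NA), def)
#' @export
classify_indicator <- function(value, definition) {
  definition <- as.list(definition)
  if (!is.numeric(value) && !all(is.na(value))) {
    rlang::abort(paste0("non-numeric value for indicator '",
                        definition$name, "'"),
                 class = "cescore_input_error")
  }
  value <- as.numeric(value)
  if (any(!is.na(value) & !is.finite(value))) {
    rlang::abort(paste0("non-finite value for indicator '",
                        definition$name, "'"),
                 class = "cescore_input_error")
  }
  lo <- definition$cutoff_lo
  hi <- definition$cutoff_hi
  out <- rep(NA_character_, length(value))
  idx <- !is.na(value)
  v <- value[idx]
  lv <- if (definition$direction == "higher_is_worse") {
    ifelse(v >= hi, "extreme", ifelse(v >= lo, "high", "low_medium"))
  } else {
    ifelse(v <= hi, "extreme", ifelse(v <= lo, "high", "low_medium"))
  }
  out[idx] <- lv
  out
}

#' Missing-data policy for scoring
#'
#' Controls what happens when an indicator level cannot be resolved. Under
#' `strict` (the default) any unresolved level leaves the dimension sum and
#' the severity score unresolved. `impute_extreme` substitutes the extreme
#' level for missing indicators — the documented exception the model allows
#' when the context is known to be dire — and `impute_level` substitutes an
#' arbitrary configured level. Every substitution is recorded in the scored
#' output.
#'
#' @param mode `"strict"`, `"impute_extreme"` or `"impute_level"`.
#' @param impute_as Level to substitute; required when `mode =
#'   "impute_level"`. `impute_extreme` is shorthand for `impute_level` with
#'   `impute_as = "extreme"`.
#' @return A list with class `cescore_missing_policy`.
#' @export
missing_policy <- function(mode = c("strict", "impute_extreme", "impute_level"),
                           impute_as = NULL) {
  mode <- match.arg(mode)
  if (mode == "impute_extreme") {
    impute_as <- "extreme"
  } else if (mode == "impute_level") {
    if (is.null(impute_as)) {
      rlang::abort("impute_level requires impute_as",
                   class = "cescore_config_error")
    }
    assert_level(impute_as)
  } else {
    impute_as <- NULL
  }
  structure(list(mode = mode, impute_as = impute_as),
            class = "cescore_missing_policy")
}

as_missing_policy <- function(policy) {
  if (inherits(policy, "cescore_missing_policy")) return(policy)
  if (is.character(policy) && length(policy) == 1L) {
    # accept CLI-style hyphens
    return(missing_policy(gsub("-", "_", policy)))
  }
  rlang::abort("invalid missing policy", class = "cescore_config_error")
}

#' Sum the weights of one dimension's four levels
#'
#' @param levels Character vector of exactly four levels, `NA` allowed.
#' @param policy A [missing_policy()] (or its mode as a string).
#' @return A list: `sum` (numeric in `[2, 6]`, or `NA` when unresolved under
#'   the strict policy), and `imputed` (logical vector flagging substituted
#'   slots).
#' @examples
#' dimension_sum(c("extreme", "extreme", "extreme", NA),
#'               missing_policy("impute_extreme"))
#' @export
dimension_sum <- function(levels, policy = missing_policy("strict")) {
  if (length(levels) != 4L) {
    rlang::abort("a dimension has exactly 4 indicator levels",
                 class = "cescore_input_error")
  }
  assert_level(levels)
  policy <- as_missing_policy(policy)
  imputed <- rep(FALSE, 4L)
  miss <- is.na(levels)
  if (any(miss)) {
    if (policy$mode == "strict") {
      return(list(sum = NA_real_, imputed = imputed))
    }
    levels[miss] <- policy$impute_as
    imputed <- miss
  }
  list(sum = sum(level_weight(levels)), imputed = imputed)
}

#' Severity score: vulnerability times exposure
#'
#' The two dimension sums each lie in `[2, 6]` (four weights of 0.5-1.5), so
#' the product lies in `[4, 36]`: 4 is the lowest attainable severity and 36
#' the highest.
#'
#' @param vulnerability_sum,exposure_sum Numeric vectors of dimension sums.
#' @return Numeric vector of severity scores; `NA` where either sum is `NA`.
#' @examples
#' severity_score(2, 2)   # lowest attainable: 4
#' severity_score(6, 6)   # highest attainable: 36
#' severity_score(6, 5.5) # 33
#' @export
severity_score <- function(vulnerability_sum, exposure_sum) {
  for (s in list(vulnerability_sum, exposure_sum)) {
    if (any(!is.na(s) & (s < 2 | s > 6))) {
      rlang::abort("dimension sums must lie in [2, 6]",
                   class = "cescore_input_error")
    }
  }
  vulnerability_sum * exposure_sum
}

#' Need score: severity times millions of people in need
#'
#' @param severity Numeric severity scores in `[4, 36]`.
#' @param people_in_need_millions Non-negative numeric, millions of people in
#'   need of (or affected by, in older appeals) humanitarian assistance.
#' @return Numeric vector of need scores; zero iff nobody is in need.
#' @examples
#' need_score(33, 3.2)
#' @export
need_score <- function(severity, people_in_need_millions) {
  if (any(!is.na(severity) & (severity < 4 | severity > 36))) {
    rlang::abort("severity scores must lie in [4, 36]",
                 class = "cescore_input_error")
  }
  if (any(!is.na(people_in_need_millions) & people_in_need_millions < 0)) {
    rlang::abort("people_in_need_millions must be non-negative",
                 class = "cescore_input_error")
  }
  severity * people_in_need_millions
}

#' Score one country-year record
#'
#' Composes the full pipeline: classify each raw indicator value against its
#' cut-offs, map levels to weights, sum the vulnerability and exposure
#' weights separately, multiply the two sums into the severity score, and
#' multiply by millions of people in need into the need score. Missing
#' indicator values are handled per `policy`; a missing people-in-need figure
#' leaves the need score unresolved while severity may still resolve.
#'
#' @param record A list or one-row data frame with fields `country`,
#'   `assessment_date`, one element/column per configured indicator name
#'   (`NA` = not available), and optionally `population` and
#'   `people_in_need_millions`.
#' @param config A `cescore_config` (default: [default_model_config()]).
#' @param policy A [missing_policy()].
#' @return A one-row tibble: `country`, `assessment_date`, one `level_<name>`
#'   column per indicator, `vulnerability_sum`, `exposure_sum`,
#'   `severity_score`, `need_score`, and semicolon-joined
#'   `imputed_indicators` / `missing_indicators`.
#' @examples
#' rec <- list(country = "Ukraine", assessment_date = "2015-01",
#'             gni_per_capita_ppp = 8500, adult_literacy = 99,
#'             child_underweight = 2, life_expectancy = 71,
#'             uprooted_number = 60000, uprooted_proportion = 0.2,
#'             people_in_need_number = 500000,
#'             people_in_need_proportion = 1.1,
#'             people_in_need_millions = 1.0)
#' score_country(rec)
#' @export
score_country <- function(record, config = default_model_config(),
                          policy = missing_policy("strict")) {
  config <- validate_model_config(config)
  policy <- as_missing_policy(policy)
  record <- as.list(record)

  known <- c("country", "assessment_date", "population",
             "people_in_need_millions")
  extra <- setdiff(names(record), c(known, config$name))
  if (length(extra) > 0L) {
    rlang::abort(paste0("unknown indicator name(s): ",
                        paste(extra, collapse = ", ")),
                 class = "cescore_config_error")
  }

  levels <- vapply(seq_len(nrow(config)), function(i) {
    nm <- config$name[i]
    v <- if (is.null(record[[nm]])) NA_real_ else record[[nm]]
    classify_indicator(v, config[i, ])
  }, character(1))
  names(levels) <- config$name

  missing_ind <- config$name[is.na(levels)]

  vuln_idx <- config$dimension == "vulnerability"
  vs <- dimension_sum(levels[vuln_idx], policy)
  es <- dimension_sum(levels[!vuln_idx], policy)
  imputed_ind <- c(config$name[vuln_idx][vs$imputed],
                   config$name[!vuln_idx][es$imputed])

  sev <- if (is.na(vs$sum) || is.na(es$sum)) NA_real_
         else severity_score(vs$sum, es$sum)

  pin <- record$people_in_need_millions
  pin <- if (is.null(pin) || is.na(pin)) NA_real_ else as.numeric(pin)
  need <- if (is.na(sev) || is.na(pin)) NA_real_ else need_score(sev, pin)

  out <- tibble::tibble(
    country = as.character(record$country %||% NA_character_),
    assessment_date = as.character(record$assessment_date %||% NA_character_),
    vulnerability_sum = vs$sum,
    exposure_sum = es$sum,
    severity_score = sev,
    need_score = need,
    people_in_need_millions = pin,
    imputed_indicators = paste(imputed_ind, collapse = ";"),
    missing_indicators = paste(missing_ind, collapse = ";")
  )
  lev_cols <- tibble::as_tibble(as.list(levels))
  names(lev_cols) <- paste0("level_", config$name)
  dplyr::bind_cols(out[, 1:2], lev_cols, out[, -(1:2)])
}

#' Score a panel of country-year records
#'
#' @param panel A data frame with columns `country`, `assessment_date` (or
#'   `date`), one column per configured indicator, and optionally
#'   `population` and `people_in_need_millions` — the shape read by
#'   [read_panel()].
#' @inheritParams score_country
#' @return A tibble with one scored row per input row (see
#'   [score_country()]), ordered by country then date.
#' @export
score_panel <- function(panel, config = default_model_config(),
                        policy = missing_policy("strict")) {
  config <- validate_model_config(config)
  if (nrow(panel) == 0L) {
    rlang::abort("empty input panel", class = "cescore_input_error")
  }
  if ("date" %in% names(panel) && !"assessment_date" %in% names(panel)) {
    names(panel)[names(panel) == "date"] <- "assessment_date"
  }
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    score_country(panel[i, , drop = FALSE], config, policy)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$country, out$assessment_date), ]
}

#' Median of per-sector affected counts
#'
#' When an appeal reports the number of people affected per intervention
#' sector rather than overall, the sector counts overlap and their sum
#' overstates the total; a median across sectors is used instead. For an even
#' number of sectors the lower of the two central values is returned by
#' default, since appeal figures are integer head-counts; set
#' `rule = "interpolate"` for the conventional midpoint.
#'
#' @param counts Numeric vector of per-sector affected counts (at least one).
#' @param rule `"lower"` (default) or `"interpolate"`.
#' @return A single number.
#' @examples
#' median_affected(c(1, 3, 9))      # 3
#' median_affected(c(2, 4, 6, 8))   # 4 (lower central value)
#' @export
median_affected <- function(counts, rule = c("lower", "interpolate")) {
  rule <- match.arg(rule)
  if (length(counts) == 0L || !is.numeric(counts) || anyNA(counts)) {
    rlang::abort("counts must be a non-empty numeric vector without NA",
                 class = "cescore_input_error")
  }
  if (rule == "interpolate") return(stats::median(counts))
  s <- sort(counts)
  s[[ceiling(length(s) / 2)]]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
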