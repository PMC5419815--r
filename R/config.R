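#' Define one scoring indicator
#'
#' An indicator definition carries the indicator's identity, the dimension it
#' contributes to (vulnerability or exposure), the direction in which raw
#' values get worse, and the two cut-offs separating the three severity
#' levels in the indicator's native units.
#'
#' For a `higher_is_worse` indicator, `cutoff_lo < cutoff_hi` and values below
#' `cutoff_lo` are low/medium, values from `cutoff_lo` up to (but excluding)
#' `cutoff_hi` are high, and values at or above `cutoff_hi` are extreme. For a
#' `lower_is_worse` indicator the comparisons are mirrored, so
#' `cutoff_lo > cutoff_hi`. A value exactly at a cut-off is always assigned
#' the more severe side.
#'
#' @param name Indicator name (used as the CSV column name).
#' @param dimension `"vulnerability"` or `"exposure"`.
#' @param direction `"higher_is_worse"` or `"lower_is_worse"`.
#' @param cutoff_lo Boundary between low/medium and high, native units.
#' @param cutoff_hi Boundary between high and extreme, native units.
#' @param units Optional free-text units, for documentation only.
#' @return A one-row tibble.
#' @examples
#' indicator_definition("child_underweight", "vulnerability",
#'                      "higher_is_worse", cutoff_lo = 20, cutoff_hi = 30)
#' @export
indicator_definition <- function(name, dimension, direction,
                                 cutoff_lo, cutoff_hi, units = NA_character_) {
  dimension <- match.arg(dimension, c("vulnerability", "exposure"))
  direction <- match.arg(direction, c("higher_is_worse", "lower_is_worse"))
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    rlang::abort("indicator name must be a non-empty string",
                 class = "cescore_config_error")
  }
  for (x in list(cutoff_lo, cutoff_hi)) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      rlang::abort(paste0("cut-offs for '", name, "' must be finite numbers"),
                   class = "cescore_config_error")
    }
  }
  ok <- if (direction == "higher_is_worse") cutoff_lo < cutoff_hi else cutoff_lo > cutoff_hi
  if (!ok) {
    rlang::abort(
      paste0("indicator '", name, "' (", direction, "): cut-offs must satisfy ",
             if (direction == "higher_is_worse") "cutoff_lo < cutoff_hi"
             else "cutoff_lo > cutoff_hi"),
      class = "cescore_config_error"
    )
  }
  tibble::tibble(
    name = name, dimension = dimension, direction = direction,
    cutoff_lo = as.numeric(cutoff_lo), cutoff_hi = as.numeric(cutoff_hi),
    units = units
  )
}

#' Assemble and validate a model configuration
#'
#' A valid configuration has exactly four vulnerability and four exposure
#' indicator definitions with unique names.
#'
#' @param definitions A tibble of indicator definitions (rows as produced by
#'   [indicator_definition()]) or a list of such one-row tibbles.
#' @return A tibble with class `cescore_config`.
#' @export
model_config <- function(definitions) {
  if (is.list(definitions) && !is.data.frame(definitions)) {
    definitions <- dplyr::bind_rows(definitions)
  }
  # force a full revalidation even on previously validated objects
  class(definitions) <- setdiff(class(definitions), "cescore_config")
  validate_model_config(definitions)
}

#' @rdname model_config
#' @param config A candidate configuration tibble.
#' @export
validate_model_config <- function(config) {
  # already validated by construction; skip the per-row rechecks
  if (inherits(config, "cescore_config")) return(config)
  required <- c("name", "dimension", "direction", "cutoff_lo", "cutoff_hi")
  missing_cols <- setdiff(required, names(config))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("model configuration lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "cescore_config_error")
  }
  if (anyDuplicated(config$name)) {
    rlang::abort(paste0("duplicate indicator name(s): ",
                        paste(unique(config$name[duplicated(config$name)]),
                              collapse = ", ")),
                 class = "cescore_config_error")
  }
  # re-run the per-indicator checks so hand-edited configs are caught
  rows <- lapply(seq_len(nrow(config)), function(i) {
    indicator_definition(config$name[i], config$dimension[i],
                         config$direction[i], config$cutoff_lo[i],
                         config$cutoff_hi[i],
                         if ("units" %in% names(config)) config$units[i]
                         else NA_character_)
  })
  config <- dplyr::bind_rows(rows)
  counts <- table(factor(config$dimension,
                         levels = c("vulnerability", "exposure")))
  if (counts[["vulnerability"]] != 4L || counts[["exposure"]] != 4L) {
    rlang::abort(
      paste0("a model configuration needs exactly 4 vulnerability and 4 ",
             "exposure indicators; got ", counts[["vulnerability"]],
             " and ", counts[["exposure"]]),
      class = "cescore_config_error"
    )
  }
  # canonical order: vulnerability block first, then exposure
  config <- config[order(match(config$dimension,
                               c("vulnerability", "exposure"))), ]
  class(config) <- c("cescore_config", class(config))
  config
}

#' Read a model configuration from YAML or JSON
#'
#' The file holds a top-level `indicators` list of eight blocks, each with
#' `name`, `dimension`, `direction`, `cutoff_lo`, `cutoff_hi` and an optional
#' `units` field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `cescore_config` tibble.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("model configuration file not found: ", path),
                 class = "cescore_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
    else yaml::read_yaml(path),
    error = function(e) {
      rlang::abort(paste0("cannot parse model configuration '", path, "': ",
                          conditionMessage(e)),
                   class = "cescore_config_error")
    }
  )
  if (is.null(raw$indicators)) {
    rlang::abort(paste0("model configuration '", path,
                        "' lacks an 'indicators' list"),
                 class = "cescore_config_error")
  }
  rows <- lapply(raw$indicators, function(b) {
    for (f in c("name", "dimension", "direction", "cutoff_lo", "cutoff_hi")) {
      if (is.null(b[[f]])) {
        rlang::abort(paste0("indicator block missing field '", f, "' in ",
                            path),
                     class = "cescore_config_error")
      }
    }
    indicator_definition(b$name, b$dimension, b$direction,
                         b$cutoff_lo, b$cutoff_hi,
                         if (is.null(b$units)) NA_character_ else b$units)
  })
  model_config(rows)
}

#' Write a model configuration to YAML
#'
#' @param config A `cescore_config` tibble.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  config <- validate_model_config(config)
  blocks <- lapply(seq_len(nrow(config)), function(i) {
    b <- list(name = config$name[i], dimension = config$dimension[i],
              direction = config$direction[i],
              cutoff_lo = config$cutoff_lo[i], cutoff_hi = config$cutoff_hi[i])
    if (!is.na(config$units[i])) b$units <- config$units[i]
    b
  })
  yaml::write_yaml(list(indicators = blocks), path)
  invisible(path)
}

#' The default model configuration
#'
#' Ships with the package as an editable YAML file
#' (`system.file("extdata", "default_model.yaml", package = "cescore")`).
#' Three vulnerability indicators (GNI per capita at PPP, adult literacy,
#' child underweight) and three exposure indicators (number and proportion of
#' uprooted people, number of people in need) are standard choices for this
#' kind of composite index; the fourth slot of each dimension (life
#' expectancy at birth; proportion of the population in need) is a documented
#' placeholder. The cut-off values are provisional, drawn from typical
#' least-developed-country ranges, and are expected to be reviewed and edited
#' for any real assessment.
#'
#' @return A validated `cescore_config` tibble.
#' @export
default_model_config <- function() {
  read_model_config(system.file("extdata", "default_model.yaml",
                                package = "cescore", mustWork = TRUE))
}

#' Names of the indicators in a configuration, in canonical order
#'
#' @param config A `cescore_config` tibble.
#' @return Character vector, vulnerability indicators first.
#' @export
indicator_names <- function(config) {
  validate_model_config(config)$name
}
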