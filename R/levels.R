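#' Ordinal severity levels
#'
#' Indicator values are classified into one of three ordered severity levels.
#' Each level carries a fixed numeric weight used in the dimension sums:
#' low/medium = 0.5, high = 1.0, extreme = 1.5.
#'
#' @format A character vector of the three level names, mildest first.
#' @export
severity_levels <- c("low_medium", "high", "extreme")

# weight lookup; the bijection level <-> weight is part of the model contract
.level_weights <- c(low_medium = 0.5, high = 1.0, extreme = 1.5)

#' Validate severity level labels
#'
#' @param level Character vector of level labels (may contain `NA`).
#' @return The input, checked; an error names any invalid label.
#' @keywords internal
assert_level <- function(level) {
  bad <- !is.na(level) & !(level %in% severity_levels)
  if (any(bad)) {
    rlang::abort(
      paste0(
        "invalid severity level(s): ",
        paste(unique(level[bad]), collapse = ", "),
        " (expected one of ", paste(severity_levels, collapse = ", "), ")"
      ),
      class = "cescore_input_error"
    )
  }
  invisible(level)
}

#' Numeric weight of a severity level
#'
#' Maps the ordinal severity levels to their scoring weights:
#' `low_medium` -> 0.5, `high` -> 1.0, `extreme` -> 1.5. Missing levels map
#' to `NA`.
#'
#' @param level Character vector of levels (`"low_medium"`, `"high"`,
#'   `"extreme"`), possibly `NA`.
#' @return Numeric vector of weights of the same length.
#' @examples
#' level_weight(c("low_medium", "high", "extreme"))
#' @export
level_weight <- function(level) {
  assert_level(level)
  out <- unname(.level_weights[level])
  out[is.na(level)] <- NA_real_
  out
}

#' Severity level as an ordered factor
#'
#' @param level Character vector of level labels.
#' @return An ordered factor with levels `low_medium < high < extreme`.
#' @export
as_severity_level <- function(level) {
  assert_level(level)
  factor(level, levels = severity_levels, ordered = TRUE)
}
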