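#' Reliability check: severity scores versus excess mortality
#'
#' Excess mortality (direct plus indirect deaths per 100,000 persons per
#' year) is a recognised, if late and noisy, measure of how severe a complex
#' emergency is. This check asks whether the model's severity ranking of a
#' set of emergencies agrees with their excess-mortality ranking. It reports
#' Spearman's rank correlation (average ranks for ties) together with a
#' rank-window concordance: a context is concordant when its severity rank
#' and mortality rank differ by at most `window` positions, and discordant
#' otherwise.
#'
#' @param scored A data frame with columns `context` and `severity_score`
#'   (a scored panel whose `country` column holds the context label also
#'   works).
#' @param mortality A data frame with columns `context` and
#'   `excess_mortality_per_100k_year` (see [read_mortality()]).
#' @param window Maximum allowed rank difference for a context to count as
#'   concordant (default 1).
#' @return A list of class `cescore_validation`: `n_contexts`,
#'   `rank_correlation`, `n_concordant`, `discordant_contexts`, `window`,
#'   and the joined `table`.
#' @examples
#' sc <- data.frame(context = letters[1:5], severity_score = c(4, 9, 16, 25, 33))
#' mo <- data.frame(context = letters[1:5],
#'                  excess_mortality_per_100k_year = c(10, 30, 80, 200, 500))
#' compare_with_mortality(sc, mo)
#' @export
compare_with_mortality <- function(scored, mortality, window = 1) {
  if (!"context" %in% names(scored) && "country" %in% names(scored)) {
    scored$context <- scored$country
  }
  if (!all(c("context", "severity_score") %in% names(scored))) {
    rlang::abort("scored input needs columns context and severity_score",
                 class = "cescore_input_error")
  }
  if (!all(c("context", "excess_mortality_per_100k_year") %in%
           names(mortality))) {
    rlang::abort(
      "mortality input needs columns context and excess_mortality_per_100k_year",
      class = "cescore_input_error")
  }
  unmatched <- c(setdiff(scored$context, mortality$context),
                 setdiff(mortality$context, scored$context))
  if (length(unmatched) > 0L) {
    rlang::abort(paste0("unmatched context(s): ",
                        paste(unique(unmatched), collapse = ", ")),
                 class = "cescore_input_error")
  }
  tab <- dplyr::inner_join(
    scored[, c("context", "severity_score")],
    mortality[, c("context", "excess_mortality_per_100k_year")],
    by = "context"
  )
  # canonical order so the result cannot depend on input row order
  tab <- tab[order(tab$context), ]
  n <- nrow(tab)
  if (n < 3L) {
    rlang::abort("need at least 3 matched contexts",
                 class = "cescore_input_error")
  }
  if (anyNA(tab$severity_score)) {
    rlang::abort(paste0("unresolved severity score for: ",
                        paste(tab$context[is.na(tab$severity_score)],
                              collapse = ", ")),
                 class = "cescore_input_error")
  }
  tab$severity_rank <- rank(tab$severity_score) # average ranks for ties
  tab$mortality_rank <- rank(tab$excess_mortality_per_100k_year)
  rho <- stats::cor(tab$severity_score,
                    tab$excess_mortality_per_100k_year,
                    method = "spearman")
  tab$rank_gap <- abs(tab$severity_rank - tab$mortality_rank)
  discordant <- tab$context[tab$rank_gap > window]
  structure(
    list(
      n_contexts = n,
      rank_correlation = rho,
      n_concordant = n - length(discordant),
      discordant_contexts = discordant,
      window = window,
      table = tibble::as_tibble(tab)
    ),
    class = "cescore_validation"
  )
}

#' @export
print.cescore_validation <- function(x, ...) {
  cat("Severity vs excess-mortality reliability check\n")
  cat(sprintf("  contexts:          %d\n", x$n_contexts))
  cat(sprintf("  Spearman rho:      %.3f\n", x$rank_correlation))
  cat(sprintf("  concordant (rank gap <= %g): %d of %d\n",
              x$window, x$n_concordant, x$n_contexts))
  if (length(x$discordant_contexts) > 0L) {
    cat("  discordant:        ",
        paste(x$discordant_contexts, collapse = ", "), "\n")
  }
  invisible(x)
}
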