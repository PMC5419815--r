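#' Specification for a synthetic country-year panel
#'
#' Describes a simulated assessment round with known ground truth: how many
#' countries and years, the marginal distribution of true severity levels per
#' indicator, the probability that a raw indicator value is unavailable, the
#' range (in millions) of people in need, and the log-normal noise applied
#' when pairing severities with synthetic excess-mortality rates.
#'
#' The defaults emulate a typical assessment round: 16 countries followed
#' over 3 years; levels drawn 45/35/20 percent low-medium/high/extreme so
#' panels mix all three colours; 5 percent of indicator values unavailable
#' (most data is obtainable, a few cells are blank); people in need between
#' 0.1 and 12 million, the span seen across contemporary appeals.
#'
#' @param n_countries,n_years Panel dimensions.
#' @param level_distribution Probabilities of `low_medium`, `high`,
#'   `extreme` for every indicator (must sum to 1).
#' @param missingness_rate Probability in `[0, 1)` that an indicator value is
#'   recorded as not available.
#' @param in_need_range Interval (millions) for the people-in-need draw.
#' @param mortality_noise_sd Standard deviation of the log-normal noise in
#'   [generate_mortality()]; 0 gives mortality strictly co-monotone with
#'   severity.
#' @param seed Integer seed; fully determines the output. Separate substreams
#'   are derived for levels, missingness and mortality noise so each can be
#'   regenerated independently.
#' @return A list with class `cescore_sim_spec`.
#' @export
simulation_spec <- function(n_countries = 16, n_years = 3,
                            level_distribution = c(low_medium = 0.45,
                                                   high = 0.35,
                                                   extreme = 0.20),
                            missingness_rate = 0.05,
                            in_need_range = c(0.1, 12),
                            mortality_noise_sd = 0.3,
                            seed = 1L) {
  if (n_countries < 1 || n_years < 1) {
    rlang::abort("n_countries and n_years must be at least 1",
                 class = "cescore_config_error")
  }
  if (length(level_distribution) != 3L || any(level_distribution < 0) ||
      abs(sum(level_distribution) - 1) > 1e-8) {
    rlang::abort("level_distribution must be 3 probabilities summing to 1",
                 class = "cescore_config_error")
  }
  names(level_distribution) <- severity_levels
  if (missingness_rate < 0 || missingness_rate >= 1) {
    rlang::abort("missingness_rate must lie in [0, 1)",
                 class = "cescore_config_error")
  }
  if (length(in_need_range) != 2L || any(in_need_range < 0) ||
      in_need_range[1] > in_need_range[2]) {
    rlang::abort("in_need_range must be a non-negative interval",
                 class = "cescore_config_error")
  }
  if (mortality_noise_sd < 0) {
    rlang::abort("mortality_noise_sd must be non-negative",
                 class = "cescore_config_error")
  }
  structure(
    list(n_countries = as.integer(n_countries), n_years = as.integer(n_years),
         level_distribution = level_distribution,
         missingness_rate = missingness_rate,
         in_need_range = as.numeric(in_need_range),
         mortality_noise_sd = mortality_noise_sd, seed = as.integer(seed)),
    class = "cescore_sim_spec"
  )
}

# independent substream seeds derived once from the main seed
sub_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  list(levels = s[1], missing = s[2], noise = s[3])
}

# the open interval of raw values classifying to each level; the bins beyond
# the outer cut-offs are bounded by one cut-off span so draws stay finite
level_interval <- function(definition, level) {
  lo <- definition$cutoff_lo
  hi <- definition$cutoff_hi
  span <- abs(hi - lo)
  if (definition$direction == "higher_is_worse") {
    switch(level,
           low_medium = c(lo - span, lo),
           high = c(lo, hi),
           extreme = c(hi, hi + span))
  } else {
    switch(level,
           low_medium = c(lo, lo + span),
           high = c(hi, lo),
           extreme = c(hi - span, hi))
  }
}

#' Generate a synthetic country-year panel with known ground truth
#'
#' True severity levels are drawn per indicator from the spec's level
#' distribution; a raw value is then drawn uniformly inside the open interval
#' of that level's cut-off bin (respecting the indicator's direction), which
#' guarantees that classifying the value recovers the level exactly.
#' Missingness is applied afterwards, so the ground truth keeps the full
#' level assignment.
#'
#' @param spec A [simulation_spec()].
#' @param config The model configuration whose cut-offs shape the raw values.
#' @return A list: `records` — a tibble in the input-panel shape (one row per
#'   country-year, raw values with `NA` where masked); `truth` — a tibble of
#'   the drawn levels (`level_<name>`), the true dimension sums and the true
#'   severity per row.
#' @export
generate_panel <- function(spec, config = default_model_config()) {
  stopifnot(inherits(spec, "cescore_sim_spec"))
  config <- validate_model_config(config)
  ss <- sub_seeds(spec$seed)

  countries <- sprintf("country_%02d", seq_len(spec$n_countries))
  years <- as.character(seq(2013, length.out = spec$n_years))
  grid <- expand.grid(country = countries, assessment_date = years,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$country, grid$assessment_date), ]
  n <- nrow(grid)
  k <- nrow(config)

  set.seed(ss$levels)
  levels_mat <- matrix(
    sample(severity_levels, n * k, replace = TRUE,
           prob = spec$level_distribution),
    nrow = n, ncol = k, dimnames = list(NULL, config$name)
  )
  values_mat <- matrix(NA_real_, n, k, dimnames = list(NULL, config$name))
  for (j in seq_len(k)) {
    ivals <- vapply(levels_mat[, j], function(lv) {
      iv <- level_interval(config[j, ], lv)
      stats::runif(1, iv[1], iv[2])
    }, numeric(1))
    values_mat[, j] <- ivals
  }
  population <- round(stats::runif(n, 1e6, 5e7))
  pin <- round(stats::runif(n, spec$in_need_range[1], spec$in_need_range[2]), 2)

  set.seed(ss$missing)
  if (spec$missingness_rate > 0) {
    mask <- matrix(stats::runif(n * k) < spec$missingness_rate, n, k)
    values_mat[mask] <- NA_real_
  }

  records <- dplyr::bind_cols(
    tibble::as_tibble(grid),
    tibble::as_tibble(as.data.frame(values_mat)),
    tibble::tibble(population = population, people_in_need_millions = pin)
  )

  w <- matrix(level_weight(levels_mat), n, k)
  vuln <- config$dimension == "vulnerability"
  vsum <- rowSums(w[, vuln, drop = FALSE])
  esum <- rowSums(w[, !vuln, drop = FALSE])
  truth_levels <- tibble::as_tibble(as.data.frame(levels_mat))
  names(truth_levels) <- paste0("level_", config$name)
  truth <- dplyr::bind_cols(
    tibble::as_tibble(grid), truth_levels,
    tibble::tibble(vulnerability_sum = vsum, exposure_sum = esum,
                   severity_score = vsum * esum)
  )
  list(records = records, truth = truth)
}

#' Generate synthetic excess-mortality rates paired to true severities
#'
#' Mortality is a monotone increasing map of true severity multiplied by
#' log-normal noise: `rate = 8 * exp(severity / 8) * exp(noise)` with `noise
#' ~ Normal(0, mortality_noise_sd)`. With zero noise the rates are strictly
#' co-monotone with severity, so the rank correlation against the model's
#' scores is exactly 1.
#'
#' @param truth The `truth` tibble from [generate_panel()] (or any data frame
#'   with `country`, `assessment_date`, `severity_score`).
#' @param spec The [simulation_spec()] (supplies noise sd and seed).
#' @return A tibble with `context` (country and date) and
#'   `excess_mortality_per_100k_year`.
#' @export
generate_mortality <- function(truth, spec) {
  stopifnot(inherits(spec, "cescore_sim_spec"))
  if (anyNA(truth$severity_score)) {
    rlang::abort("true severities must be resolved",
                 class = "cescore_input_error")
  }
  ss <- sub_seeds(spec$seed)
  set.seed(ss$noise)
  n <- nrow(truth)
  noise <- if (spec$mortality_noise_sd > 0) {
    stats::rnorm(n, 0, spec$mortality_noise_sd)
  } else {
    rep(0, n)
  }
  base <- 8 * exp(truth$severity_score / 8)
  tibble::tibble(
    context = paste(truth$country, truth$assessment_date),
    excess_mortality_per_100k_year = base * exp(noise)
  )
}
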