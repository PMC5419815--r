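# shared fixtures: all built in code at test time

test_config <- function() default_model_config()

# a complete record whose eight values classify to the given levels under the
# default configuration, by drawing the midpoint of each level's bin
record_at_levels <- function(levels, country = "X", date = "2015-01",
                             people_in_need_millions = 1.0,
                             config = test_config()) {
  stopifnot(length(levels) == nrow(config))
  vals <- lapply(seq_len(nrow(config)), function(i) {
    lv <- levels[i]
    if (is.na(lv)) return(NA_real_)
    iv <- cescore:::level_interval(config[i, ], lv)
    mean(iv)
  })
  names(vals) <- config$name
  c(list(country = country, assessment_date = date,
         people_in_need_millions = people_in_need_millions), vals)
}

# independent brute-force scorer: classify each value directly against the
# cut-offs with plain comparisons, then sum and multiply; no package scoring
# functions are used
brute_force_severity <- function(record, config = test_config()) {
  w <- vapply(seq_len(nrow(config)), function(i) {
    v <- record[[config$name[i]]]
    if (is.null(v) || is.na(v)) return(NA_real_)
    lo <- config$cutoff_lo[i]; hi <- config$cutoff_hi[i]
    if (config$direction[i] == "higher_is_worse") {
      if (v >= hi) 1.5 else if (v >= lo) 1.0 else 0.5
    } else {
      if (v <= hi) 1.5 else if (v <= lo) 1.0 else 0.5
    }
  }, numeric(1))
  vs <- sum(w[config$dimension == "vulnerability"])
  es <- sum(w[config$dimension == "exposure"])
  vs * es
}

# first-principles Spearman: average ranks, then the Pearson formula on them
brute_force_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

random_levels <- function(n = 8) {
  sample(severity_levels, n, replace = TRUE)
}

write_temp_panel <- function(records, file = tempfile(fileext = ".csv")) {
  readr::write_csv(dplyr::bind_rows(lapply(records, tibble::as_tibble)),
                   file, na = "")
  file
}
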