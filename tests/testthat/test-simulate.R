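test_that("the same seed reproduces the panel exactly", {
  cfg <- test_config()
  a <- generate_panel(simulation_spec(n_countries = 6, seed = 21), cfg)
  b <- generate_panel(simulation_spec(n_countries = 6, seed = 21), cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- generate_panel(simulation_spec(n_countries = 6, seed = 22), cfg)
  expect_false(identical(a$records, c$records))
})

test_that("with zero missingness, scoring recovers the true severity exactly", {
  cfg <- test_config()
  spec <- simulation_spec(n_countries = 40, n_years = 2,
                          missingness_rate = 0, seed = 5)
  sim <- generate_panel(spec, cfg)
  scored <- score_panel(sim$records, cfg)
  truth <- sim$truth[order(sim$truth$country, sim$truth$assessment_date), ]
  expect_identical(scored$severity_score, truth$severity_score)
  # the recovered levels match, too
  for (nm in paste0("level_", cfg$name)) {
    expect_identical(scored[[nm]], truth[[nm]])
  }
})

test_that("a degenerate extreme distribution forces severity 36 everywhere", {
  cfg <- test_config()
  spec <- simulation_spec(n_countries = 10, n_years = 1,
                          level_distribution = c(0, 0, 1),
                          missingness_rate = 0, seed = 3)
  sim <- generate_panel(spec, cfg)
  scored <- score_panel(sim$records, cfg)
  expect_true(all(scored$severity_score == 36))
})

test_that("empirical missingness matches the requested rate", {
  cfg <- test_config()
  rate <- 0.1
  spec <- simulation_spec(n_countries = 150, n_years = 2,
                          missingness_rate = rate, seed = 17)
  sim <- generate_panel(spec, cfg)
  cells <- as.matrix(sim$records[, cfg$name])
  n <- length(cells)
  emp <- mean(is.na(cells))
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(emp - rate), 3 * se)
})

test_that("noiseless mortality is strictly co-monotone with severity", {
  cfg <- test_config()
  spec <- simulation_spec(n_countries = 12, n_years = 1,
                          missingness_rate = 0, mortality_noise_sd = 0,
                          seed = 9)
  sim <- generate_panel(spec, cfg)
  mort <- generate_mortality(sim$truth, spec)
  scored <- score_panel(sim$records, cfg)
  scored$context <- paste(scored$country, scored$assessment_date)
  res <- compare_with_mortality(scored, mort)
  expect_equal(res$rank_correlation, 1)
})

test_that("noise lowers the rank correlation below the noiseless limit on average", {
  cfg <- test_config()
  rhos <- vapply(seq_len(30), function(i) {
    spec <- simulation_spec(n_countries = 12, n_years = 1,
                            missingness_rate = 0, mortality_noise_sd = 2,
                            seed = 1000 + i)
    sim <- generate_panel(spec, cfg)
    mort <- generate_mortality(sim$truth, spec)
    brute_force_spearman(sim$truth$severity_score,
                         mort$excess_mortality_per_100k_year)
  }, numeric(1))
  expect_lt(mean(rhos), 0.95)
  expect_gt(mean(rhos), 0) # still positively related
})

test_that("tied severities are handled without error", {
  cfg <- test_config()
  spec <- simulation_spec(n_countries = 8, n_years = 1,
                          level_distribution = c(1, 0, 0),
                          missingness_rate = 0, mortality_noise_sd = 0.5,
                          seed = 2)
  sim <- generate_panel(spec, cfg)
  mort <- generate_mortality(sim$truth, spec)
  scored <- score_panel(sim$records, cfg)
  scored$context <- paste(scored$country, scored$assessment_date)
  res <- suppressWarnings(compare_with_mortality(scored, mort))
  expect_true(is.finite(res$rank_correlation) || is.na(res$rank_correlation))
})

test_that("invalid simulation specs are rejected", {
  expect_error(simulation_spec(n_countries = 0), class = "cescore_config_error")
  expect_error(simulation_spec(level_distribution = c(0.5, 0.5, 0.5)),
               class = "cescore_config_error")
  expect_error(simulation_spec(missingness_rate = 1),
               class = "cescore_config_error")
  expect_error(simulation_spec(in_need_range = c(5, 1)),
               class = "cescore_config_error")
  expect_error(simulation_spec(mortality_noise_sd = -1),
               class = "cescore_config_error")
})
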