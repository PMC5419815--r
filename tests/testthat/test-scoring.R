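test_that("classification respects cut-offs, direction and the severe-boundary convention", {
  up <- indicator_definition("underweight", "vulnerability",
                             "higher_is_worse", cutoff_lo = 20, cutoff_hi = 30)
  down <- indicator_definition("literacy", "vulnerability",
                               "lower_is_worse", cutoff_lo = 70, cutoff_hi = 45)

  expect_equal(classify_indicator(c(5, 19.99, 20, 25, 29.99, 30, 99), up),
               c("low_medium", "low_medium", "high", "high", "high",
                 "extreme", "extreme"))
  # mirrored direction: values above cutoff_lo are mild, at/below cutoff_hi extreme
  expect_equal(classify_indicator(c(95, 70.01, 70, 50, 45, 44, 10), down),
               c("low_medium", "low_medium", "high", "high", "extreme",
                 "extreme", "extreme"))
  # na propagates
  expect_true(is.na(classify_indicator(NA, up)))
  # non-finite values are rejected with the indicator named
  expect_error(classify_indicator(Inf, up), "underweight",
               class = "cescore_input_error")
  expect_error(classify_indicator("abc", up), class = "cescore_input_error")
})

test_that("level weights are the fixed 0.5 / 1.0 / 1.5 bijection", {
  expect_equal(level_weight(c("low_medium", "high", "extreme")),
               c(0.5, 1.0, 1.5))
  expect_true(is.na(level_weight(NA_character_)))
  expect_error(level_weight("catastrophic"), class = "cescore_input_error")
  expect_true(all(diff(level_weight(severity_levels)) > 0)) # order-preserving
})

test_that("dimension sums cover the [2, 6] range and honour the missing policy", {
  expect_equal(dimension_sum(rep("low_medium", 4))$sum, 2)
  expect_equal(dimension_sum(rep("extreme", 4))$sum, 6)

  with_na <- c("extreme", "extreme", "extreme", NA)
  strict <- dimension_sum(with_na, missing_policy("strict"))
  expect_true(is.na(strict$sum))
  expect_false(any(strict$imputed))

  imput <- dimension_sum(with_na, missing_policy("impute_extreme"))
  expect_equal(imput$sum, 6)
  expect_equal(which(imput$imputed), 4L)

  as_low <- dimension_sum(with_na, missing_policy("impute_level",
                                                  impute_as = "low_medium"))
  expect_equal(as_low$sum, 5)

  expect_error(dimension_sum(rep("high", 3)), class = "cescore_input_error")
  expect_error(missing_policy("impute_level"), class = "cescore_config_error")
})

test_that("severity and need scores multiply as defined with range contracts", {
  expect_equal(severity_score(2, 2), 4)
  expect_equal(severity_score(6, 6), 36)
  expect_equal(severity_score(6, 5.5), 33)
  expect_error(severity_score(1.5, 4), class = "cescore_input_error")
  expect_error(severity_score(4, 6.5), class = "cescore_input_error")

  expect_equal(need_score(4, 0), 0)
  expect_equal(need_score(10, 2.5), 25)
  expect_equal(need_score(36, 1), 36)
  expect_error(need_score(10, -1), class = "cescore_input_error")
  expect_error(need_score(40, 1), class = "cescore_input_error")
})

test_that("score_country composes classification, sums and products", {
  cfg <- test_config()

  all_yellow <- record_at_levels(rep("low_medium", 8),
                                 people_in_need_millions = 1.0)
  s <- score_country(all_yellow, cfg)
  expect_equal(s$severity_score, 4)
  expect_equal(s$need_score, 4)
  expect_equal(s$missing_indicators, "")

  # one vulnerability value unavailable, imputed extreme; exposure 3 extreme + 1 high
  lv <- c("extreme", "extreme", "extreme", NA,
          "extreme", "extreme", "extreme", "high")
  rec <- record_at_levels(lv, country = "ctx", people_in_need_millions = 3.2)
  strict <- score_country(rec, cfg, missing_policy("strict"))
  expect_true(is.na(strict$severity_score))
  expect_match(strict$missing_indicators, "life_expectancy")

  imputed <- score_country(rec, cfg, missing_policy("impute_extreme"))
  expect_equal(imputed$severity_score, 33)
  expect_equal(imputed$vulnerability_sum, 6)
  expect_equal(imputed$exposure_sum, 5.5)
  expect_equal(imputed$imputed_indicators, "life_expectancy")
  expect_equal(imputed$need_score, 33 * 3.2)

  # all values absent under strict: severity absent, all 8 flagged
  empty <- record_at_levels(rep(NA_character_, 8))
  se <- score_country(empty, cfg)
  expect_true(is.na(se$severity_score))
  expect_equal(length(strsplit(se$missing_indicators, ";")[[1]]), 8L)

  # severity may resolve while need stays open
  no_pin <- record_at_levels(rep("high", 8), people_in_need_millions = NA)
  sn <- score_country(no_pin, cfg)
  expect_equal(sn$severity_score, 16)
  expect_true(is.na(sn$need_score))

  expect_error(score_country(c(all_yellow, list(mystery_indicator = 5)), cfg),
               "mystery_indicator", class = "cescore_config_error")
})

test_that("score_country agrees with an independent brute-force recomputation", {
  cfg <- test_config()
  set.seed(42)
  for (i in seq_len(200)) {
    rec <- record_at_levels(random_levels())
    expect_equal(score_country(rec, cfg)$severity_score,
                 brute_force_severity(rec, cfg))
  }
})

test_that("severity is symmetric in its dimensions and dominated by extreme imputation", {
  set.seed(11)
  for (i in seq_len(50)) {
    a <- sum(level_weight(random_levels(4)))
    b <- sum(level_weight(random_levels(4)))
    expect_identical(severity_score(a, b), severity_score(b, a))
  }
  # imputation dominance on records with holes
  cfg <- test_config()
  for (i in seq_len(25)) {
    lv <- random_levels()
    lv[sample(8, sample(1:3, 1))] <- NA
    rec <- record_at_levels(lv)
    hi <- score_country(rec, cfg, missing_policy("impute_extreme"))$severity_score
    lo <- score_country(rec, cfg,
                        missing_policy("impute_level",
                                       impute_as = "low_medium"))$severity_score
    expect_gte(hi, lo)
  }
})

test_that("raising any single indicator level strictly increases severity", {
  set.seed(99)
  cfg <- test_config()
  vuln <- cfg$dimension == "vulnerability"
  for (i in seq_len(100)) {
    lv <- random_levels()
    w <- level_weight(lv)
    base <- severity_score(sum(w[vuln]), sum(w[!vuln]))
    for (j in which(lv != "extreme")) {
      esc <- lv
      esc[j] <- severity_levels[match(lv[j], severity_levels) + 1L]
      w2 <- level_weight(esc)
      expect_gt(severity_score(sum(w2[vuln]), sum(w2[!vuln])), base)
    }
  }
})

test_that("median of per-sector affected counts uses the lower central value", {
  expect_equal(median_affected(5), 5)
  expect_equal(median_affected(c(1, 3, 9)), 3)
  expect_equal(median_affected(c(2, 4, 6, 8)), 4)
  expect_equal(median_affected(c(2, 4, 6, 8), rule = "interpolate"),
               stats::median(c(2, 4, 6, 8)))
  # odd length agrees with the reference implementation
  expect_equal(median_affected(c(7, 1, 5)), stats::median(c(7, 1, 5)))
  expect_error(median_affected(numeric(0)), class = "cescore_input_error")
})
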