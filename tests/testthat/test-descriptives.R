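test_that("cut-off systems apply their sex-specific thresholds and comparators", {
  expect_equal(classify_abdominal_obesity(90.0, "male", "IDF"), 1L)
  expect_equal(classify_abdominal_obesity(89.9, "male", "IDF"), 0L)
  expect_equal(classify_abdominal_obesity(80.0, "female", "IDF"), 1L)
  expect_equal(classify_abdominal_obesity(79.9, "female", "IDF"), 0L)
  # ATP III thresholds are strict
  expect_equal(classify_abdominal_obesity(102.0, "male", "ATPIII"), 0L)
  expect_equal(classify_abdominal_obesity(102.1, "male", "ATPIII"), 1L)
  expect_equal(classify_abdominal_obesity(88.0, "female", "ATPIII"), 0L)
  # LASO thresholds are inclusive
  expect_equal(classify_abdominal_obesity(97.0, "male", "LASO"), 1L)
  expect_equal(classify_abdominal_obesity(94.0, "female", "LASO"), 1L)
  expect_equal(classify_abdominal_obesity(93.9, "female", "LASO"), 0L)
  # missing waist propagates, never silently negative
  expect_true(is.na(classify_abdominal_obesity(NA, "male", "IDF")))
  expect_error(classify_abdominal_obesity(-3, "male", "IDF"),
               class = "ineq_data_error")
  # vectorized over mixed sexes
  expect_equal(
    classify_abdominal_obesity(c(91, 79, 85), c("male", "female", "female"),
                               cutoff_criterion("IDF")),
    c(1L, 0L, 1L)
  )
})

test_that("weighted prevalence reproduces hand-computed weighted means", {
  ds <- make_dataset(n = 4, ao = c(1, 1, 0, 0))
  ds$ao <- c(1L, 1L, 0L, 0L)
  expect_equal(weighted_prevalence(ds, "ao")$estimate, 0.5)

  ds2 <- make_dataset(n = 2, weight = c(3, 1))
  ds2$ao <- c(1L, 0L)
  expect_equal(weighted_prevalence(ds2, "ao")$estimate, 0.75)

  # all-positive outcome: degenerate interval [1, 1]
  ds3 <- make_dataset(n = 3)
  ds3$ao <- c(1L, 1L, 1L)
  row <- weighted_prevalence(ds3, "ao")
  expect_equal(c(row$estimate, row$ci_low, row$ci_high), c(1, 1, 1))

  expect_error(weighted_prevalence(ds, "ao", by = "nope"),
               class = "ineq_config_error")
})

test_that("prevalence is invariant to positive weight rescaling and CIs are proper", {
  set.seed(11)
  ds <- make_dataset(n = 400, wealth = rnorm(400),
                     weight = rgamma(400, 4, scale = 0.25),
                     grp = sample(c("a", "b"), 400, TRUE))
  ds$ao <- rbinom(400, 1, 0.35)
  for (method in c("taylor", "wilson")) {
    t1 <- weighted_prevalence(ds, "ao", by = "grp", ci_method = method)
    ds_scaled <- ds
    ds_scaled$weight <- ds$weight * 13.7
    t2 <- weighted_prevalence(ds_scaled, "ao", by = "grp", ci_method = method)
    expect_equal(t1$estimate, t2$estimate)
    expect_equal(t1$ci_low, t2$ci_low)
    expect_true(all(t1$ci_low <= t1$estimate & t1$estimate <= t1$ci_high))
    expect_true(all(t1$ci_low >= 0 & t1$ci_high <= 1))
  }
})

test_that("Taylor-linearized intervals use the PSU/stratum design when present", {
  des <- synthetic_design(
    n = 4000, seed = 3,
    weight_model = list(type = "design", strata = 6, psu_per_stratum = 8,
                        psu_sd = 0.6)
  )
  pop <- generate_population(des)
  with_design <- weighted_prevalence(pop, "abdominal_obesity")
  no_design <- tibble::as_tibble(pop)
  no_design$psu <- NULL; no_design$stratum <- NULL
  srs <- weighted_prevalence(survey_dataset(no_design), "abdominal_obesity")
  expect_equal(with_design$estimate, srs$estimate)
  # clustering on wealth-correlated PSUs widens the interval
  expect_gt(with_design$ci_high - with_design$ci_low,
            srs$ci_high - srs$ci_low)
})

test_that("weighted means and their SEs follow the same machinery", {
  ds <- make_dataset(n = 2, waist = c(90, 94))
  expect_equal(weighted_mean_se(ds, "waist_cm")$mean, 92)
  ds2 <- make_dataset(n = 2, waist = c(80, 100), weight = c(1, 3))
  expect_equal(weighted_mean_se(ds2, "waist_cm")$mean, 95)
  # single-record cell: mean returned, SE undefined
  one <- weighted_mean_se(make_dataset(n = 1, waist = 88), "waist_cm")
  expect_equal(one$mean, 88)
  expect_true(is.na(one$se))
  # missing values excluded cell-wise
  ds3 <- make_dataset(n = 3, waist = c(90, NA, 100))
  expect_equal(weighted_mean_se(ds3, "waist_cm")$n_unweighted, 2L)
})

test_that("cell estimates converge to a constant outcome probability", {
  des <- plain_design(n = 30000, seed = 47, slope = 0, intercept = qlogis(0.3))
  pop <- generate_population(des)
  pop$cell <- factor(rep(c("c1", "c2", "c3"), length.out = nrow(pop)))
  tab <- weighted_prevalence(survey_dataset(tibble::as_tibble(pop)),
                             "abdominal_obesity", by = "cell")
  for (i in seq_len(nrow(tab))) {
    se <- (tab$ci_high[i] - tab$ci_low[i]) / (2 * qnorm(0.975))
    expect_lt(abs(tab$estimate[i] - 0.3), 3 * se)
  }
})

test_that("standard populations validate and age-standardization averages", {
  expect_error(standard_population(c(18, 30), c(0.6, 0.5)),
               class = "ineq_config_error")
  std <- standard_population(c(18, 30, 60), c(0.3, 0.5, 0.2))
  # constant prevalence is reproduced exactly
  expect_equal(age_standardize(c(`18` = 0.4, `30` = 0.4, `60` = 0.4), std), 0.4)
  # hand-computed two-band average
  std2 <- standard_population(c(18, 60), c(0.6, 0.4))
  expect_equal(age_standardize(c(`18` = 0.5, `60` = 1.0), std2), 0.7)
  # band mismatch is a configuration error
  expect_error(age_standardize(c(`18` = 0.5, `45` = 1.0), std2),
               class = "ineq_config_error")
  # result bounded by the band estimates
  est <- c(`18` = 0.21, `30` = 0.74, `60` = 0.55)
  val <- age_standardize(est, std)
  expect_true(val >= min(est) && val <= max(est))
})

test_that("the WHO world standard loads, normalizes, and merges onto adult bands", {
  std <- who_standard_population()
  expect_equal(sum(std$weight), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(std$age_low, strictly = TRUE))
  merged <- who_standard_population(breaks = c(18, 30, 60))
  expect_equal(merged$age_low, c(18L, 30L, 60L))
  expect_equal(sum(merged$weight), 1, tolerance = 1e-12)
  # adults 30-59 outweigh 60+ in the world standard
  expect_gt(merged$weight[2], merged$weight[3])
})
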