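sim_with_covariates <- function(n, seed, rank_slope = 0, urban_coef = 0,
                                urban_slope = 3) {
  synthetic_design(
    n = n, seed = seed, sex_split = 0.5,
    covariate_models = list(
      area = list(levels = c("rural", "urban"), base_probs = c(0.4, 0.6),
                  slope = urban_slope),
      smoker = list(levels = c("no", "yes"), base_probs = c(0.85, 0.15),
                    slope = 0.3)
    ),
    outcome_model = list(
      intercept = c(male = -0.3, female = -0.3),
      rank_slope = rank_slope,
      coef = list(area = c(urban = urban_coef))
    ),
    waist_model = NULL, prop_pregnant = 0
  )
}

test_that("partial effect matches a finite-difference of the fitted response", {
  pop <- generate_population(sim_with_covariates(8000, seed = 3,
                                                 urban_coef = 0.8))
  pe <- fit_partial_effects(pop, "abdominal_obesity", c("area", "smoker"))
  cf <- coef(pe$model)
  mm <- model.matrix(pe$model)
  w <- pop$weight / mean(pop$weight)
  xbar <- colSums(w * mm) / sum(w)
  for (term in pe$effects$term) {
    h <- 1e-5
    xp <- xbar; xp[term] <- xp[term] + h
    xm <- xbar; xm[term] <- xm[term] - h
    fd <- (plogis(sum(cf * xp)) - plogis(sum(cf * xm))) / (2 * h)
    expect_equal(pe$effects$partial_effect[pe$effects$term == term], fd,
                 tolerance = 1e-6)
  }
  # dummy means are the weighted shares of the non-reference levels
  expect_equal(pe$effects$x_bar[pe$effects$term == "areaurban"],
               sum(w * (pop$area == "urban")) / sum(w))
})

test_that("a covariate with zero true effect shows a null partial effect", {
  pop <- generate_population(sim_with_covariates(50000, seed = 9,
                                                 rank_slope = 1.5,
                                                 urban_coef = 0.8))
  pe <- fit_partial_effects(pop, "abdominal_obesity", c("area", "smoker"))
  s <- summary(pe$model)$coefficients
  z <- s["smokeryes", "Estimate"] / s["smokeryes", "Std. Error"]
  expect_lt(abs(z), 3)
})

test_that("an intercept-only specification yields a valid empty effect set", {
  pop <- generate_population(sim_with_covariates(500, seed = 2))
  pe <- fit_partial_effects(pop, "abdominal_obesity", character())
  expect_equal(nrow(pe$effects), 0L)
  expect_true(pe$p_bar > 0 && pe$p_bar < 1)
})

test_that("reference levels can be chosen and are excluded from the rows", {
  pop <- generate_population(sim_with_covariates(2000, seed = 4,
                                                 urban_coef = 0.5))
  pe <- fit_partial_effects(pop, "abdominal_obesity", c("area", "smoker"),
                            refs = c(area = "urban"))
  expect_true("arearural" %in% pe$effects$term)
  expect_false("areaurban" %in% pe$effects$term)
  expect_equal(unname(pe$refs["area"]), "urban")
})

test_that("decomposition rows satisfy their defining identities", {
  pop <- generate_population(sim_with_covariates(10000, seed = 5,
                                                 rank_slope = 1,
                                                 urban_coef = 0.8))
  # include wealth quintiles among the regressors so that the direct wealth
  # gradient is captured by the covariates rather than left in the residual
  pop$wealth_quintile <- assign_wealth_quintiles(pop)
  pop <- survey_dataset(tibble::as_tibble(pop))
  dec <- decompose_eci(pop, "abdominal_obesity",
                       c("wealth_quintile", "area", "smoker"))
  rows <- dec$rows
  expect_equal(rows$contribution, rows$elasticity * rows$ci_k,
               tolerance = 1e-12)
  expect_equal(rows$pct_contribution,
               100 * rows$contribution / dec$total_eci, tolerance = 1e-9)
  expect_equal(rows$elasticity, 4 * rows$partial_effect * rows$x_bar,
               tolerance = 1e-12)
  # closure: contributions + residual = total, gap recorded as zero
  expect_equal(sum(rows$contribution) + dec$residual, dec$total_eci,
               tolerance = 1e-12)
  expect_equal(dec$adds_up_gap, 0)
  # the total matches the standalone Erreygers index on the same data
  ro <- ranked_outcome(pop$abdominal_obesity, pop$wealth_score, pop$weight)
  expect_equal(dec$total_eci, erreygers_index(ro)$value, tolerance = 1e-10)
  # residual via the error-term generalized CI stays small for a
  # well-specified logistic data-generating process
  expect_lt(abs(dec$residual), 0.1 * abs(dec$total_eci))
  expect_equal(dec$residual, dec$residual_gci, tolerance = 0.02)
})

test_that("a pro-rich, outcome-increasing covariate contributes positively", {
  pop <- generate_population(sim_with_covariates(20000, seed = 6,
                                                 urban_coef = 1.2,
                                                 urban_slope = 3.5))
  dec <- decompose_eci(pop, "abdominal_obesity", c("area", "smoker"))
  urban <- dec$rows[dec$rows$level == "urban", ]
  expect_gt(urban$partial_effect, 0)
  expect_gt(urban$ci_k, 0)
  expect_gt(urban$contribution, 0)
})

test_that("adding-up validation flags tampered rows and accepts honest ones", {
  pop <- generate_population(sim_with_covariates(4000, seed = 8,
                                                 urban_coef = 0.7))
  dec <- decompose_eci(pop, "abdominal_obesity", c("area", "smoker"))
  rep_ok <- validate_adding_up(dec)
  expect_true(rep_ok$ok)
  expect_lt(abs(rep_ok$gap), 1e-12)

  rows <- dec$rows
  rows$contribution[1] <- rows$contribution[1] + 0.05
  rep_bad <- validate_adding_up(rows, residual = dec$residual,
                                total_eci = dec$total_eci)
  expect_false(rep_bad$ok)
  expect_equal(rep_bad$flagged_rows, 1L)
  expect_error(validate_adding_up(rows), class = "ineq_config_error")
})

test_that("published reference rows obey the row identity at printed precision", {
  ref <- reference_decomposition()
  expect_equal(nrow(ref), 40L)
  chk <- validate_adding_up(ref, residual = 0, total_eci = 0, tol = 1e-3)
  expect_equal(chk$flagged_rows, integer(0))
  # the worked-example products: richest men and married/cohabiting women
  men_rich <- ref[ref$sex == "men" & ref$level == "richest", ]
  expect_lt(abs(men_rich$elasticity * men_rich$ci_k - 0.127), 1e-3)
  wom_marr <- ref[ref$sex == "women" & ref$level == "married_cohabiting", ]
  expect_lt(abs(wom_marr$elasticity * wom_marr$ci_k - (-0.024)), 1e-3)
})

test_that("perfect separation is reported as an estimation error", {
  n <- 400
  ds <- make_dataset(n = n, wealth = rnorm(n),
                     grp = rep(c("a", "b"), each = n / 2))
  ds$ao <- as.integer(ds$grp == "b")
  expect_error(fit_partial_effects(ds, "ao", "grp"),
               class = "ineq_estimation_error")
})
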