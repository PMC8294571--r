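test_that("fractional ranks are cumulative-weight midpoints with shared ties", {
  expect_equal(fractional_rank(1:4), c(0.125, 0.375, 0.625, 0.875))
  expect_equal(fractional_rank(c(1, 2), c(1, 3)), c(0.125, 0.625))
  expect_equal(fractional_rank(rep(3, 5), c(5, 1, 2, 1, 7)), rep(0.5, 5))
  # order of input rows must not matter beyond alignment
  x <- c(2, -1, 5, 0)
  w <- c(1, 2, 1, 4)
  r <- fractional_rank(x, w)
  perm <- c(3, 1, 4, 2)
  expect_equal(fractional_rank(x[perm], w[perm]), r[perm])
})

test_that("weighted mean rank is 0.5 and ranks stay inside (0,1)", {
  for (seed in 1:20) {
    d <- random_ranked(n = 37, seed)
    r <- fractional_rank(d$wealth, d$w)
    wn <- d$w / sum(d$w)
    expect_lt(abs(sum(wn * r) - 0.5), 1e-10)
    expect_true(all(r > 0 & r < 1))
  }
})

test_that("concentration index matches direct hand evaluation", {
  # richer of two equal-weight records has the outcome
  ro <- ranked_outcome(c(0, 1), c(1, 2))
  expect_equal(concentration_index(ro)$value, 0.5)
  # reversing the wealth ordering flips the sign
  ro_rev <- ranked_outcome(c(0, 1), c(2, 1))
  expect_equal(concentration_index(ro_rev)$value, -0.5)
  # constant outcome: zero covariance
  ro_const <- ranked_outcome(rep(1, 6), 1:6)
  expect_equal(concentration_index(ro_const)$value, 0)
  expect_true(concentration_index(ro_const)$degenerate)
  # zero mean leaves the index undefined
  expect_error(concentration_index(ranked_outcome(rep(0, 4), 1:4)),
               class = "ineq_estimation_error")
})

test_that("Erreygers index scales the CI by 4*mu/(b-a)", {
  ro <- ranked_outcome(c(0, 1), c(1, 2))
  expect_equal(erreygers_index(ro)$value, 1.0)
  expect_equal(erreygers_index(ranked_outcome(rep(1, 5), 1:5))$value, 0)
  for (seed in 1:10) {
    d <- random_ranked(n = 60, seed)
    if (sum(d$y) %in% c(0, length(d$y))) next
    ro <- ranked_outcome(d$y, d$wealth, d$w)
    ci <- concentration_index(ro)$value
    eci <- erreygers_index(ro)$value
    expect_lt(abs(eci - 4 * ro$mu * ci), 1e-10)
  }
  bad <- ranked_outcome(c(0, 1), c(1, 2), bounds = c(0.5, 0.5))
  expect_error(erreygers_index(bad), class = "ineq_estimation_error")
})

test_that("covariance formula agrees exactly with the brute-force double sum", {
  wealth <- c(3, 1, 4, 1.5, 9, 2.6)
  for (bits in 1:63) {  # every non-zero binary assignment over 6 records
    y <- as.integer(intToBits(bits))[1:6]
    ro <- ranked_outcome(y, wealth)
    expect_equal(concentration_index(ro)$value, brute_force_ci(y, wealth),
                 tolerance = 1e-13)
  }
})

test_that("index equals the convenient-regression slope on random data", {
  for (seed in 1:100) {
    d <- random_ranked(n = 50, seed)
    if (sum(d$y) == 0) next
    ro <- ranked_outcome(d$y, d$wealth, d$w)
    rbar <- sum(ro$w * ro$R)
    s2r <- sum(ro$w * (ro$R - rbar)^2)
    lhs <- 2 * s2r * ro$y / ro$mu
    slope <- unname(coef(lm(lhs ~ ro$R, weights = ro$w))[2])
    expect_lt(abs(concentration_index(ro)$value - slope), 1e-10)
  }
})

test_that("indices are invariant to monotone wealth transforms and weight scale", {
  for (seed in 1:10) {
    d <- random_ranked(n = 80, seed)
    if (sum(d$y) == 0) next
    base <- concentration_index(ranked_outcome(d$y, d$wealth, d$w))$value
    trans <- concentration_index(
      ranked_outcome(d$y, exp(3 * d$wealth) + 10, d$w))$value
    scaled <- concentration_index(ranked_outcome(d$y, d$wealth, 7.3 * d$w))$value
    expect_lt(abs(base - trans), 1e-12)
    expect_lt(abs(base - scaled), 1e-12)
    eci <- erreygers_index(ranked_outcome(d$y, d$wealth, d$w))$value
    eci_t <- erreygers_index(ranked_outcome(d$y, exp(d$wealth), 0.2 * d$w))$value
    expect_lt(abs(eci - eci_t), 1e-12)
  }
})

test_that("concentration curve cumulates outcome shares in wealth order", {
  # constant outcome: the diagonal
  ro <- ranked_outcome(rep(1, 4), c(4, 2, 3, 1))
  curve <- concentration_curve(ro)
  expect_equal(curve$outcome_share, curve$pop_share)
  # pro-rich two-record example passes through (0.5, 0)
  ro2 <- ranked_outcome(c(0, 1), c(1, 2))
  c2 <- concentration_curve(ro2)
  expect_equal(c2$pop_share, c(0, 0.5, 1))
  expect_equal(c2$outcome_share, c(0, 0, 1))
  # reversing wealth rotates the curve through (1/2, 1/2): each point (x, y)
  # maps to (1-x, 1-y), carrying a pro-rich curve into its pro-poor mirror
  c3 <- concentration_curve(ranked_outcome(c(1, 0), c(1, 2)))
  expect_equal(c3$pop_share, rev(1 - c2$pop_share))
  expect_equal(c3$outcome_share, rev(1 - c2$outcome_share))
  # endpoints exact, both coordinates monotone
  d <- random_ranked(n = 40, seed = 3)
  cc <- concentration_curve(ranked_outcome(d$y, d$wealth, d$w))
  expect_equal(cc$pop_share[1], 0)
  expect_equal(cc$outcome_share[nrow(cc)], 1)
  expect_true(!is.unsorted(cc$pop_share) && !is.unsorted(cc$outcome_share))
  expect_error(concentration_curve(ranked_outcome(rep(0, 3), 1:3)),
               class = "ineq_estimation_error")
})

test_that("one minus twice the curve area recovers the index", {
  for (seed in 1:10) {
    d <- random_ranked(n = 200, seed)
    ro <- ranked_outcome(d$y, d$wealth, d$w)
    auc <- curve_auc(concentration_curve(ro))
    expect_lt(abs(concentration_index(ro)$value - (1 - 2 * auc)), 1e-6)
  }
})

test_that("convenient-regression SE behaves like a sampling standard error", {
  d <- random_ranked(n = 200, seed = 5)
  ro <- ranked_outcome(d$y, d$wealth, d$w)
  se1 <- index_standard_error(ro, "ECI")
  dup <- ranked_outcome(rep(d$y, 2), rep(d$wealth, 2), rep(d$w, 2))
  se2 <- index_standard_error(dup, "ECI")
  expect_equal(se2 / se1, 1 / sqrt(2), tolerance = 0.02)

  # constant outcome: zero SE
  expect_equal(index_standard_error(ranked_outcome(rep(1, 10), 1:10), "CI"), 0)
})

test_that("analytic SE agrees with a bootstrap on moderate samples", {
  des <- plain_design(n = 5000, seed = 31, slope = 1.5)
  pop <- generate_population(des)
  ro <- ranked_outcome(pop$abdominal_obesity, pop$wealth_score, pop$weight)
  se <- index_standard_error(ro, "ECI")
  set.seed(99)
  boots <- replicate(500, {
    idx <- sample.int(nrow(pop), replace = TRUE)
    rb <- ranked_outcome(pop$abdominal_obesity[idx], pop$wealth_score[idx],
                         pop$weight[idx])
    erreygers_index(rb)$value
  })
  expect_equal(se, sd(boots), tolerance = 0.1)
})

test_that("cluster-robust SE needs clusters and at least two of them", {
  d <- random_ranked(n = 40, seed = 8)
  ro <- ranked_outcome(d$y, d$wealth, d$w)
  expect_error(index_standard_error(ro, "CI", method = "cluster_robust"),
               class = "ineq_config_error")
  ro_one <- ranked_outcome(d$y, d$wealth, d$w,
                           cluster = rep("c1", length(d$y)))
  expect_error(index_standard_error(ro_one, "CI", method = "cluster_robust"),
               class = "ineq_estimation_error")
  ro_cl <- ranked_outcome(d$y, d$wealth, d$w,
                          cluster = rep(c("c1", "c2", "c3", "c4"), 10))
  expect_gt(index_standard_error(ro_cl, "CI", method = "cluster_robust"), 0)
})
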