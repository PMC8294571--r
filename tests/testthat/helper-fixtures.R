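# shared fixtures: tiny in-memory datasets and independent oracles

make_dataset <- function(n = 8, wealth = seq_len(n), weight = rep(1, n),
                         sex = rep(c("male", "female"), length.out = n),
                         age = rep(40L, n), waist = rep(95, n),
                         year = "y1", ...) {
  survey_dataset(tibble::tibble(
    person_id = as.character(seq_len(n)), year = year,
    sex = sex, age_years = age, waist_cm = waist,
    wealth_score = wealth, weight = weight, ...
  ))
}

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

default_schema <- c(id = "pid", sex = "sex", age = "age", waist = "waist",
                    wealth = "wealth", weight = "wt")

fixture_raw_rows <- function() {
  data.frame(
    pid = 1:5, sex = c("male", "female", "male", "female", "male"),
    age = c(25L, 34L, 47L, 61L, 19L),
    waist = c(91.2, 78.5, 103.0, 88.1, 96.4),
    wealth = c(-0.5, 0.3, 1.2, -1.1, 0.0),
    wt = c(1.2, 0.8, 1.0, 1.5, 0.9)
  )
}

# brute-force concentration index: (1/mu) * double sum over pairs of the
# weighted covariance, independent of the covariance implementation
brute_force_ci <- function(y, wealth, w = rep(1, length(y))) {
  wn <- w / sum(w)
  r <- fractional_rank(wealth, w)
  mu <- sum(wn * y)
  cov <- 0
  for (i in seq_along(y)) {
    for (j in seq_along(y)) {
      cov <- cov + wn[i] * wn[j] * (y[i] - y[j]) * (r[i] - r[j])
    }
  }
  (2 / mu) * (cov / 2)
}

# random weighted binary dataset for equivalence sweeps
random_ranked <- function(n, seed) {
  set.seed(seed)
  list(
    y = rbinom(n, 1, 0.4),
    wealth = rnorm(n),
    w = rgamma(n, shape = 3, scale = 0.5)
  )
}

# design with no covariate effects and a chosen wealth-rank slope
plain_design <- function(n, seed, slope, intercept = 0,
                         weight_model = list(type = "gamma", shape = 4,
                                             scale = 0.25)) {
  synthetic_design(
    n = n, seed = seed, sex_split = 0.5,
    weight_model = weight_model,
    covariate_models = list(),
    outcome_model = list(intercept = c(male = intercept, female = intercept),
                         rank_slope = slope, coef = list()),
    waist_model = NULL, prop_pregnant = 0
  )
}
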