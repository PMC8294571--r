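#' Parameterize an ENDES-like synthetic population
#'
#' Fully specifies a generator of survey microdata with a known, controllable
#' socioeconomic gradient in a binary abdominal-obesity outcome. The
#' structure emulates a national demographic health survey: a continuous
#' wealth score, expansion-factor weights, categorical covariates whose
#' distributions shift with wealth, a logistic outcome model on the weighted
#' wealth *rank* (so the implied concentration structure is invariant to the
#' shape of the wealth distribution), and an optional continuous waist
#' circumference for exercising cut-off classifiers.
#'
#' Each stochastic component draws from its own seeded stream (a documented
#' string-hash offset of the global seed), so adding or removing a covariate
#' never perturbs the draws of other components.
#'
#' @param n Number of respondents.
#' @param seed Global integer seed.
#' @param sex_split Proportion female, in (0, 1).
#' @param wealth_model List: `type` `"normal"` or `"lognormal"`, with `mean`,
#'   `sd` on the underlying normal.
#' @param weight_model List: `type` `"constant"`; `"gamma"` with `shape`,
#'   `scale` (mean `shape*scale`); or `"design"` with `strata`,
#'   `psu_per_stratum`, `psu_sd` (a PSU-level shift of the wealth score,
#'   inducing within-PSU wealth correlation) plus gamma weight noise.
#' @param covariate_models Named list; each element is a list with `levels`
#'   (category labels, ordered), `base_probs` (category probabilities at the
#'   median wealth rank, summing to 1) and `slope` (a single log-odds shift
#'   per unit wealth rank in a proportional-odds model; positive moves mass
#'   to later levels among the wealthy). Defaults mirror the eight covariate
#'   groups of the Peruvian adult population: age group, marital status,
#'   education, natural region, urban/rural area, altitude band, chronic
#'   disease, smoking.
#' @param outcome_model List: `intercept` named `c(male=, female=)`,
#'   `rank_slope` (log-odds per unit wealth rank; either a scalar or a named
#'   `c(male=, female=)` pair), `coef` named list of per-level log-odds
#'   (reference levels omitted or 0).
#' @param waist_model Optional list with per-sex `mean`, `sd`, `gradient`
#'   (cm per unit wealth rank, centred); `NULL` suppresses the waist column.
#' @param prop_pregnant Proportion of women flagged pregnant (exercises
#'   eligibility filtering); 0 suppresses the column.
#' @param year_label Value for the `year` column.
#'
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(n = 10000L,
                             seed = 2018L,
                             sex_split = 0.569,
                             wealth_model = list(type = "normal", mean = 0, sd = 1),
                             weight_model = list(type = "gamma", shape = 4,
                                                 scale = 0.25),
                             covariate_models = default_covariate_models(),
                             outcome_model = default_outcome_model(),
                             waist_model = default_waist_model(),
                             prop_pregnant = 0.02,
                             year_label = "synthetic") {
  design <- list(
    n = as.integer(n), seed = as.integer(seed), sex_split = sex_split,
    wealth_model = wealth_model, weight_model = weight_model,
    covariate_models = covariate_models, outcome_model = outcome_model,
    waist_model = waist_model, prop_pregnant = prop_pregnant,
    year_label = year_label
  )
  validate_design(design)
  structure(design, class = "synthetic_design")
}

#' Default covariate models of the synthetic design
#'
#' Eight categorical covariates with marginal category shares close to those
#' observed among Peruvian adults (2018-2019 pooled rounds) and a single
#' proportional-odds wealth slope each: education, urban residence and
#' metropolitan region concentrate among the wealthy; high altitude and
#' rural residence among the poor.
#'
#' @return Named list of covariate model specs (see [synthetic_design()]).
#' @export
default_covariate_models <- function() {
  list(
    age_group = list(levels = c("18-29", "30-59", "60+"),
                     base_probs = c(0.27, 0.55, 0.18), slope = 0),
    marital_status = list(
      levels = c("never_married", "married_cohabiting", "separated_widowed"),
      base_probs = c(0.17, 0.66, 0.17), slope = -0.3),
    education = list(
      levels = c("no_formal", "primary", "secondary", "higher"),
      base_probs = c(0.04, 0.21, 0.40, 0.35), slope = 2.6),
    region = list(
      levels = c("jungle", "mountain", "coast", "lima"),
      base_probs = c(0.12, 0.25, 0.26, 0.37), slope = 1.6),
    area = list(levels = c("rural", "urban"),
                base_probs = c(0.19, 0.81), slope = 3.2),
    altitude = list(
      levels = c("0-499", "500-1499", "1500-2999", "3000+"),
      base_probs = c(0.66, 0.08, 0.12, 0.14), slope = -1.4),
    chronic_disease = list(levels = c("no", "yes"),
                           base_probs = c(0.77, 0.23), slope = 0.3),
    smoker = list(levels = c("no", "yes"),
                  base_probs = c(0.885, 0.115), slope = 0.4)
  )
}

#' Default outcome model of the synthetic design
#'
#' Logistic model for abdominal obesity with a pro-rich wealth-rank slope
#' that is steeper in men than in women (mirroring the much stronger male
#' socioeconomic gradient observed in Peruvian adults), sex-specific
#' intercepts yielding prevalences near 0.61 (men) and 0.85 (women), and
#' modest covariate effects (age, marriage, education, urban residence,
#' chronic disease).
#'
#' @return Outcome model spec (see [synthetic_design()]).
#' @export
default_outcome_model <- function() {
  list(
    intercept = c(male = -2.9, female = -0.7),
    rank_slope = c(male = 2.6, female = 0.7),
    coef = list(
      age_group = c("30-59" = 1.1, "60+" = 1.2),
      marital_status = c(married_cohabiting = 0.7, separated_widowed = 0.6),
      education = c(primary = 0.1, secondary = 0.15, higher = 0.35),
      area = c(urban = 0.4),
      chronic_disease = c(yes = 0.7)
    )
  )
}

#' Default waist-circumference model of the synthetic design
#'
#' Per-sex normal waist circumference whose mean rises linearly in the
#' centred wealth rank, with gradients echoing the observed poorest-richest
#' spread (about 11 cm in men, 4 cm in women).
#'
#' @return Waist model spec (see [synthetic_design()]).
#' @export
default_waist_model <- function() {
  list(male = list(mean = 93.5, sd = 10, gradient = 11),
       female = list(mean = 92.3, sd = 9, gradient = 4))
}

validate_design <- function(d) {
  stopifnot_design <- function(ok, msg) {
    if (!ok) rlang::abort(msg, class = "ineq_design_error")
  }
  stopifnot_design(length(d$n) == 1L && is.finite(d$n) && d$n > 0,
                   "n must be a positive integer")
  stopifnot_design(d$sex_split > 0 && d$sex_split < 1,
                   "sex_split must lie in (0, 1)")
  stopifnot_design(d$wealth_model$type %in% c("normal", "lognormal"),
                   "wealth_model type must be normal or lognormal")
  wm <- d$weight_model
  stopifnot_design(wm$type %in% c("constant", "gamma", "design"),
                   "weight_model type must be constant, gamma or design")
  if (wm$type == "gamma") {
    stopifnot_design(wm$shape > 0 && wm$scale > 0,
                     "gamma weight model needs positive shape and scale")
  }
  if (wm$type == "design") {
    stopifnot_design(wm$strata >= 1 && wm$psu_per_stratum >= 1 && wm$psu_sd >= 0,
                     "design weight model needs strata >= 1, psu_per_stratum >= 1, psu_sd >= 0")
  }
  for (nm in names(d$covariate_models)) {
    cm <- d$covariate_models[[nm]]
    stopifnot_design(length(cm$levels) == length(cm$base_probs),
                     paste0(nm, ": levels and base_probs differ in length"))
    stopifnot_design(all(cm$base_probs >= 0) &&
                       abs(sum(cm$base_probs) - 1) < 1e-8,
                     paste0(nm, ": base_probs must be a probability vector"))
  }
  om <- d$outcome_model
  stopifnot_design(all(c("male", "female") %in% names(om$intercept)),
                   "outcome_model intercept needs male and female entries")
  for (nm in names(om$coef)) {
    stopifnot_design(nm %in% names(d$covariate_models),
                     paste0("outcome coefficient on unknown covariate: ", nm))
    lv <- names(om$coef[[nm]])
    stopifnot_design(all(lv %in% d$covariate_models[[nm]]$levels),
                     paste0("outcome coefficient on unknown level of ", nm))
  }
  stopifnot_design(d$prop_pregnant >= 0 && d$prop_pregnant < 1,
                   "prop_pregnant must lie in [0, 1)")
  invisible(d)
}

# stable 31-bit polynomial hash of a component name, for stream splitting
stream_seed <- function(seed, component) {
  h <- 0
  for (code in utf8ToInt(component)) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

with_stream <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, component))
  expr
}

draw_proportional_odds <- function(cm, rank, u) {
  k <- length(cm$levels)
  if (k == 1L) return(factor(cm$levels[rep(1L, length(rank))], cm$levels))
  cum <- cumsum(cm$base_probs)[-k]
  cum <- pmin(pmax(cum, 1e-12), 1 - 1e-12)
  # cumulative P(level <= j | rank): positive slope shifts mass upward with rank
  idx <- rep(1L, length(rank))
  for (j in seq_len(k - 1L)) {
    pj <- stats::plogis(stats::qlogis(cum[j]) - cm$slope * (rank - 0.5))
    idx <- idx + (u > pj)
  }
  factor(cm$levels[idx], levels = cm$levels)
}

#' Generate a synthetic survey population
#'
#' Draws `design$n` respondents: sex, wealth score, expansion weights (and
#' stratum/PSU labels under the `design` weight model), the categorical
#' covariates, a binary `abdominal_obesity` outcome from the logistic model
#' on the weighted wealth rank, integer ages consistent with the drawn age
#' band, and (optionally) waist circumference and a pregnancy flag. The same
#' design always yields a bit-identical dataset.
#'
#' @param design A [synthetic_design()].
#' @return A [survey_dataset()] with an `abdominal_obesity` column.
#' @export
generate_population <- function(design) {
  validate_design(design)
  n <- design$n
  seed <- design$seed

  sex <- with_stream(seed, "sex", {
    ifelse(stats::runif(n) < design$sex_split, "female", "male")
  })

  wealth <- with_stream(seed, "wealth", {
    z <- stats::rnorm(n, design$wealth_model$mean, design$wealth_model$sd)
    if (design$wealth_model$type == "lognormal") exp(z) else z
  })

  wm <- design$weight_model
  psu <- stratum <- NULL
  if (wm$type == "design") {
    des <- with_stream(seed, "design", {
      stratum_i <- sample.int(wm$strata, n, replace = TRUE)
      psu_i <- sample.int(wm$psu_per_stratum, n, replace = TRUE)
      shift <- stats::rnorm(wm$strata * wm$psu_per_stratum, 0, wm$psu_sd)
      list(stratum = stratum_i, psu = psu_i,
           shift = shift[(stratum_i - 1L) * wm$psu_per_stratum + psu_i])
    })
    stratum <- sprintf("S%02d", des$stratum)
    psu <- sprintf("S%02d-P%03d", des$stratum, des$psu)
    wealth <- wealth + des$shift
  }
  weight <- with_stream(seed, "weight", {
    switch(wm$type,
      constant = rep(1, n),
      gamma = stats::rgamma(n, shape = wm$shape, scale = wm$scale),
      design = stats::rgamma(n, shape = 4, scale = 0.25)
    )
  })

  rank <- fractional_rank(wealth, weight)

  covs <- list()
  for (nm in names(design$covariate_models)) {
    cm <- design$covariate_models[[nm]]
    covs[[nm]] <- with_stream(seed, paste0("covariate:", nm), {
      draw_proportional_odds(cm, rank, stats::runif(n))
    })
  }

  age_years <- if ("age_group" %in% names(covs)) {
    with_stream(seed, "age", {
      lows <- c(`18-29` = 18, `30-59` = 30, `60+` = 60)
      highs <- c(`18-29` = 29, `30-59` = 59, `60+` = 80)
      g <- as.character(covs$age_group)
      lo <- lows[g]; hi <- highs[g]
      lo[is.na(lo)] <- 18; hi[is.na(hi)] <- 80
      as.integer(floor(stats::runif(n, lo, hi + 1)))
    })
  } else {
    with_stream(seed, "age", as.integer(floor(stats::runif(n, 18, 81))))
  }

  om <- design$outcome_model
  slope <- if (length(om$rank_slope) > 1L || !is.null(names(om$rank_slope))) {
    unname(om$rank_slope[sex])
  } else {
    om$rank_slope
  }
  eta <- unname(om$intercept[sex]) + slope * rank
  for (nm in names(om$coef)) {
    cf <- om$coef[[nm]]
    add <- cf[as.character(covs[[nm]])]
    add[is.na(add)] <- 0
    eta <- eta + unname(add)
  }
  outcome <- with_stream(seed, "outcome", {
    as.integer(stats::runif(n) < stats::plogis(eta))
  })

  waist <- if (!is.null(design$waist_model)) {
    with_stream(seed, "waist", {
      wmod <- design$waist_model
      mu <- ifelse(sex == "male",
                   wmod$male$mean + wmod$male$gradient * (rank - 0.5),
                   wmod$female$mean + wmod$female$gradient * (rank - 0.5))
      sd <- ifelse(sex == "male", wmod$male$sd, wmod$female$sd)
      pmax(stats::rnorm(n, mu, sd), 40)
    })
  } else {
    NA_real_
  }

  out <- tibble::tibble(
    person_id = sprintf("id%07d", seq_len(n)),
    year = design$year_label,
    sex = sex, age_years = age_years, waist_cm = waist,
    wealth_score = wealth, weight = weight
  )
  if (!is.null(psu)) { out$psu <- psu; out$stratum <- stratum }
  if (design$prop_pregnant > 0) {
    out$pregnant <- with_stream(seed, "pregnant", {
      sex == "female" & stats::runif(n) < design$prop_pregnant
    })
  }
  for (nm in names(covs)) out[[nm]] <- covs[[nm]]
  out$abdominal_obesity <- outcome
  schema <- lapply(design$covariate_models, `[[`, "levels")
  survey_dataset(out, covariates = schema)
}

#' Oracle Erreygers index of a design, by large-sample simulation
#'
#' Generates one very large population from the design (same parameters,
#' dedicated seed stream) and returns the Erreygers concentration index of
#' the outcome over the weighted wealth ranks. Serves as ground truth for
#' parameter-recovery checks at realistic sample sizes.
#'
#' @param design A [synthetic_design()].
#' @param n_oracle Simulation size (default 1e6; should greatly exceed
#'   `design$n`).
#' @return The oracle ECI (scalar).
#' @export
true_eci_by_simulation <- function(design, n_oracle = 1e6) {
  big <- design
  big$n <- as.integer(n_oracle)
  big$seed <- stream_seed(design$seed, "oracle")
  pop <- generate_population(big)
  ro <- ranked_outcome(pop$abdominal_obesity, pop$wealth_score, pop$weight,
                       bounds = c(0, 1))
  8 * rank_covariance(ro)
}
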