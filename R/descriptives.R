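#' Abdominal-obesity cut-off criteria
#'
#' Frozen sex-specific waist-circumference thresholds from the three cut-off
#' systems used for South and Central American populations:
#' * `IDF` (International Diabetes Federation): male >= 90 cm, female >= 80 cm;
#' * `ATPIII` (Third Adult Treatment Panel): male > 102 cm, female > 88 cm
#'   (strict inequalities);
#' * `LASO` (Latin American Consortium of Studies in Obesity): male >= 97 cm,
#'   female >= 94 cm.
#'
#' @param name One of `"IDF"`, `"ATPIII"`, `"LASO"`.
#' @return A `cutoff_criterion`: list with `name`, `male_threshold_cm`,
#'   `male_comparator`, `female_threshold_cm`, `female_comparator`.
#' @export
cutoff_criterion <- function(name = c("IDF", "ATPIII", "LASO")) {
  name <- match.arg(name)
  spec <- switch(name,
    IDF = list(male = c(90, 0), female = c(80, 0)),
    ATPIII = list(male = c(102, 1), female = c(88, 1)),
    LASO = list(male = c(97, 0), female = c(94, 0))
  )
  structure(
    list(
      name = name,
      male_threshold_cm = spec$male[1],
      male_comparator = if (spec$male[2] == 0) "ge" else "gt",
      female_threshold_cm = spec$female[1],
      female_comparator = if (spec$female[2] == 0) "ge" else "gt"
    ),
    class = "cutoff_criterion"
  )
}

#' Classify abdominal obesity from waist circumference
#'
#' Applies the sex-specific threshold and comparator of a cut-off criterion.
#' Missing waist values propagate as `NA` (never silently negative).
#'
#' @param waist_cm Waist circumference in centimetres (positive; `NA`
#'   allowed).
#' @param sex Character vector of `"male"`/`"female"`, recycled against
#'   `waist_cm`.
#' @param criterion A [cutoff_criterion()] or its name.
#' @return Integer vector of 0/1 (`NA` where waist is missing).
#' @export
classify_abdominal_obesity <- function(waist_cm, sex, criterion = "IDF") {
  if (is.character(criterion)) criterion <- cutoff_criterion(criterion)
  if (any(!is.na(waist_cm) & (waist_cm <= 0 | !is.finite(waist_cm)))) {
    rlang::abort("waist_cm must be positive and finite when present",
                 class = "ineq_data_error")
  }
  sex <- rep_len(as.character(sex), length(waist_cm))
  thr <- ifelse(sex == "male", criterion$male_threshold_cm,
                criterion$female_threshold_cm)
  cmp <- ifelse(sex == "male", criterion$male_comparator,
                criterion$female_comparator)
  as.integer(ifelse(cmp == "ge", waist_cm >= thr, waist_cm > thr))
}

# Taylor-linearized variance of a weighted ratio mean (Sum w y / Sum w).
# Score residuals z_i = w_i (y_i - est) / Sum w are totalled within PSU and
# the with-replacement between-PSU variance is summed over strata; records
# act as their own PSU (single stratum) when design columns are absent.
taylor_variance <- function(y, w, est, psu = NULL, stratum = NULL) {
  z <- w * (y - est) / sum(w)
  if (is.null(psu)) psu <- seq_along(y)
  if (is.null(stratum)) stratum <- rep(1L, length(y))
  key <- paste(stratum, psu, sep = "\r")
  zt <- tapply(z, key, sum)
  st <- tapply(as.character(stratum), key, `[`, 1L)
  v <- 0
  for (h in unique(st)) {
    zh <- zt[st == h]
    nh <- length(zh)
    if (nh >= 2L) v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  v
}

# Kish effective sample size for Wilson intervals on weighted proportions
effective_n <- function(w) sum(w)^2 / sum(w^2)

prevalence_one <- function(y, w, psu, stratum, ci_method, level = 0.95) {
  est <- sum(w * y) / sum(w)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  if (est %in% c(0, 1)) {
    return(c(est = est, lo = est, hi = est))
  }
  if (ci_method == "taylor") {
    se <- sqrt(taylor_variance(y, w, est, psu, stratum))
    # CI on the logit scale keeps the interval inside (0, 1)
    lgt <- stats::qlogis(est)
    se_l <- se / (est * (1 - est))
    lo <- stats::plogis(lgt - zq * se_l)
    hi <- stats::plogis(lgt + zq * se_l)
  } else {
    ne <- effective_n(w)
    ct <- stats::prop.test(est * ne, ne, conf.level = level, correct = FALSE)
    lo <- ct$conf.int[1]
    hi <- ct$conf.int[2]
  }
  c(est = est, lo = lo, hi = hi)
}

#' Survey-weighted prevalence with confidence intervals
#'
#' Weighted prevalence of a binary outcome, overall or within cells defined
#' by covariates. The 95% interval uses, by default, Taylor linearization
#' with PSU-within-stratum clustering when the dataset carries design
#' columns (each record is its own PSU otherwise), on the logit scale;
#' `ci_method = "wilson"` uses a Wilson score interval on the Kish effective
#' sample size instead. Estimates are invariant to rescaling all weights by
#' a positive constant.
#'
#' @param dataset A [survey_dataset()].
#' @param outcome Name of a binary (0/1) column.
#' @param by Character vector of covariate/grouping column names (may be
#'   empty for the overall estimate).
#' @param ci_method `"taylor"` or `"wilson"`.
#' @return Tibble with one row per cell: grouping labels, `estimate`,
#'   `ci_low`, `ci_high`, `n_unweighted`, `weighted_total`, `ci_method`.
#' @export
weighted_prevalence <- function(dataset, outcome, by = character(),
                                ci_method = c("taylor", "wilson")) {
  ci_method <- match.arg(ci_method)
  miss <- setdiff(c(outcome, by), names(dataset))
  if (length(miss) > 0L) {
    rlang::abort(paste0("unknown column(s): ", paste(miss, collapse = ", ")),
                 class = "ineq_config_error")
  }
  df <- tibble::as_tibble(dataset)
  df <- df[!is.na(df[[outcome]]), , drop = FALSE]
  y <- as.numeric(df[[outcome]])
  if (!all(y %in% c(0, 1))) {
    rlang::abort("outcome must be binary 0/1", class = "ineq_data_error")
  }
  psu <- if ("psu" %in% names(df)) df$psu else NULL
  str <- if ("stratum" %in% names(df)) df$stratum else NULL
  cells <- if (length(by) == 0L) {
    list(`(overall)` = seq_len(nrow(df)))
  } else {
    split(seq_len(nrow(df)), df[by], drop = FALSE, sep = " / ")
  }
  rows <- lapply(names(cells), function(cell) {
    idx <- cells[[cell]]
    if (length(idx) == 0L) return(NULL)
    p <- prevalence_one(y[idx], df$weight[idx], psu[idx], str[idx], ci_method)
    tibble::tibble(
      cell = cell, estimate = p[["est"]], ci_low = p[["lo"]],
      ci_high = p[["hi"]], n_unweighted = length(idx),
      weighted_total = sum(df$weight[idx]), ci_method = ci_method
    )
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) {
    rlang::warn(paste0("omitting empty cell(s): ",
                       paste(names(cells)[empty], collapse = ", ")))
  }
  dplyr::bind_rows(rows[!empty])
}

#' Survey-weighted means with standard errors
#'
#' Weighted mean of a continuous column by cell, with a Taylor-linearized
#' standard error (same variance machinery as [weighted_prevalence()]).
#' Missing values are excluded cell-wise; a single-record cell reports an
#' `NA` standard error.
#'
#' @inheritParams weighted_prevalence
#' @param value Name of a numeric column (e.g. waist circumference).
#' @return Tibble with `cell`, `mean`, `se`, `n_unweighted`, `weighted_total`.
#' @export
weighted_mean_se <- function(dataset, value, by = character()) {
  miss <- setdiff(c(value, by), names(dataset))
  if (length(miss) > 0L) {
    rlang::abort(paste0("unknown column(s): ", paste(miss, collapse = ", ")),
                 class = "ineq_config_error")
  }
  df <- tibble::as_tibble(dataset)
  df <- df[!is.na(df[[value]]), , drop = FALSE]
  if (nrow(df) == 0L) {
    rlang::abort("no non-missing values", class = "ineq_data_error")
  }
  v <- as.numeric(df[[value]])
  psu <- if ("psu" %in% names(df)) df$psu else NULL
  str <- if ("stratum" %in% names(df)) df$stratum else NULL
  cells <- if (length(by) == 0L) {
    list(`(overall)` = seq_len(nrow(df)))
  } else {
    split(seq_len(nrow(df)), df[by], drop = FALSE, sep = " / ")
  }
  rows <- lapply(names(cells), function(cell) {
    idx <- cells[[cell]]
    if (length(idx) == 0L) return(NULL)
    w <- df$weight[idx]
    m <- sum(w * v[idx]) / sum(w)
    se <- if (length(idx) < 2L) NA_real_ else {
      sqrt(taylor_variance(v[idx], w, m, psu[idx], str[idx]))
    }
    tibble::tibble(cell = cell, mean = m, se = se,
                   n_unweighted = length(idx), weighted_total = sum(w))
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) {
    rlang::warn(paste0("omitting empty cell(s): ",
                       paste(names(cells)[empty], collapse = ", ")))
  }
  dplyr::bind_rows(rows[!empty])
}

#' Standard population for direct age standardization
#'
#' @param age_low Integer vector of age-band lower bounds (ordered,
#'   increasing); each band runs to the next bound, the last is open-ended.
#' @param weight Non-negative band weights; must sum to 1 (within 1e-12)
#'   unless `renormalize = TRUE`.
#' @param label Provenance label.
#' @param renormalize Divide the weights by their sum before validating.
#' @return A `standard_population`: tibble with `age_low` and `weight`, plus
#'   a `label` attribute.
#' @export
standard_population <- function(age_low, weight, label = "custom",
                                renormalize = FALSE) {
  if (length(age_low) != length(weight) || length(weight) == 0L) {
    rlang::abort("age_low and weight must be equal-length, non-empty",
                 class = "ineq_config_error")
  }
  if (is.unsorted(age_low, strictly = TRUE)) {
    rlang::abort("age_low must be strictly increasing",
                 class = "ineq_config_error")
  }
  if (any(weight < 0)) {
    rlang::abort("standard-population weights must be non-negative",
                 class = "ineq_config_error")
  }
  if (renormalize) weight <- weight / sum(weight)
  if (abs(sum(weight) - 1) > 1e-12) {
    rlang::abort("standard-population weights must sum to 1",
                 class = "ineq_config_error")
  }
  structure(tibble::tibble(age_low = as.integer(age_low), weight = weight),
            class = c("standard_population", class(tibble::tibble())),
            label = label)
}

#' WHO world standard population (2001)
#'
#' The WHO world standard population age weights in 5-year bands (0-4 ...
#' 84, 85+), shipped as a plain-text data file and normalized to sum to 1.
#' Optionally collapsed onto coarser analysis bands (e.g. 18-29 / 30-59 /
#' 60+) by summing the standard weights of the five-year bands whose lower
#' bound falls in each analysis band, then renormalizing.
#'
#' @param breaks Optional integer vector of analysis-band lower bounds. When
#'   supplied, five-year bands below `breaks[1]` are dropped (the standard is
#'   restricted to the adult range) and the rest merged.
#' @return A [standard_population()].
#' @export
who_standard_population <- function(breaks = NULL) {
  path <- system.file("extdata", "who_standard_population_2001.csv",
                      package = "ineqdecomp", mustWork = TRUE)
  raw <- utils::read.csv(path)
  std <- standard_population(raw$age_low, raw$weight,
                             label = "WHO World Standard", renormalize = TRUE)
  if (is.null(breaks)) return(std)
  breaks <- sort(as.integer(breaks))
  keep <- std$age_low >= breaks[1]
  if (!any(keep)) {
    rlang::abort("no standard-population bands at or above the first break",
                 class = "ineq_config_error")
  }
  band <- findInterval(std$age_low[keep], breaks)
  w <- tapply(std$weight[keep], band, sum)
  standard_population(breaks, as.numeric(w), label = "WHO World Standard",
                      renormalize = TRUE)
}

#' Direct age standardization
#'
#' Weighted average of age-band-specific estimates using a fixed reference
#' population's age weights: `sum(standard_weight * band_estimate)`. The
#' result always lies between the minimum and maximum band estimate.
#'
#' @param band_estimates Named numeric vector of band-specific estimates
#'   (e.g. prevalences); names are the band lower bounds and must match the
#'   standard's bands exactly.
#' @param standard A [standard_population()].
#' @return The age-standardized estimate (scalar).
#' @export
age_standardize <- function(band_estimates, standard) {
  key <- as.character(standard$age_low)
  if (is.null(names(band_estimates)) ||
      !setequal(names(band_estimates), key) ||
      length(band_estimates) != nrow(standard)) {
    rlang::abort(
      "band estimates must carry names matching the standard's age_low bands",
      class = "ineq_config_error"
    )
  }
  sum(standard$weight * band_estimates[key])
}
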