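#' Construct a survey dataset
#'
#' A `survey_dataset` is a tibble with one row per respondent and a fixed set
#' of analysis columns: `person_id`, `year`, `sex` (`"male"`/`"female"`),
#' `age_years`, `waist_cm` (may be `NA`), `wealth_score` (continuous asset
#' index, higher = wealthier), `weight` (expansion factor), optional design
#' columns `psu` and `stratum`, an optional logical `pregnant` column, and any
#' number of categorical covariate columns declared in the covariate schema.
#'
#' Hard invariants are enforced at construction: every retained record has a
#' strictly positive weight, a finite wealth score, a waist circumference that
#' is positive and finite when present, covariate labels drawn from the
#' schema, and no duplicated `person_id` within a survey year.
#'
#' @param data A data frame with the columns described above.
#' @param covariates Named list mapping covariate column names to their
#'   ordered category labels. Defaults to the levels observed in every
#'   factor/character column that is not a reserved analysis column.
#' @param validate Check invariants (set `FALSE` only for trusted internal
#'   calls).
#'
#' @return A tibble of class `survey_dataset` with a `covariates` attribute
#'   holding the schema.
#' @export
survey_dataset <- function(data, covariates = NULL, validate = TRUE) {
  data <- tibble::as_tibble(data)
  reserved <- c(
    "person_id", "year", "sex", "age_years", "waist_cm", "wealth_score",
    "weight", "psu", "stratum", "pregnant", "wealth_quintile"
  )
  required <- c("person_id", "sex", "age_years", "wealth_score", "weight")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      paste0("survey_dataset is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "ineq_config_error"
    )
  }
  if (!"year" %in% names(data)) data$year <- "pooled"
  if (!"waist_cm" %in% names(data)) data$waist_cm <- NA_real_
  if (is.null(covariates)) {
    cand <- setdiff(names(data), reserved)
    cand <- cand[vapply(data[cand], function(x) is.character(x) || is.factor(x),
                        logical(1))]
    covariates <- lapply(data[cand], function(x) {
      if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
    })
    names(covariates) <- cand
  }
  for (nm in names(covariates)) {
    if (!nm %in% names(data)) {
      rlang::abort(paste0("covariate column not found: ", nm),
                   class = "ineq_config_error")
    }
    data[[nm]] <- factor(as.character(data[[nm]]), levels = covariates[[nm]])
  }
  if (validate) {
    if (nrow(data) == 0L) {
      rlang::abort("survey_dataset has no records", class = "ineq_data_error")
    }
    if (any(!is.finite(data$weight) | data$weight <= 0)) {
      rlang::abort("all weights must be finite and > 0",
                   class = "ineq_data_error")
    }
    if (any(!is.finite(data$wealth_score))) {
      rlang::abort("wealth_score must be finite for every record",
                   class = "ineq_data_error")
    }
    bad_waist <- !is.na(data$waist_cm) &
      (!is.finite(data$waist_cm) | data$waist_cm <= 0)
    if (any(bad_waist)) {
      rlang::abort("waist_cm must be positive and finite when present",
                   class = "ineq_data_error")
    }
    dup <- duplicated(paste(data$year, data$person_id, sep = "\r"))
    if (any(dup)) {
      rlang::abort("duplicated person_id within a survey year",
                   class = "ineq_data_error")
    }
    for (nm in names(covariates)) {
      if (anyNA(data[[nm]])) {
        rlang::abort(
          paste0("covariate '", nm, "' has labels outside its declared schema"),
          class = "ineq_data_error"
        )
      }
    }
  }
  structure(data,
            class = c("survey_dataset", class(tibble::tibble())),
            covariates = covariates)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset> ", nrow(x), " records, ",
      length(attr(x, "covariates")), " covariates, total weight ",
      format(sum(x$weight), digits = 6), "\n", sep = "")
  NextMethod()
}

#' Covariate schema of a survey dataset
#'
#' @param dataset A [survey_dataset()].
#' @return Named list of category labels per covariate.
#' @export
covariate_schema <- function(dataset) attr(dataset, "covariates")

# keep class + schema when dplyr/row-subsetting strips attributes
restore_survey <- function(data, template) {
  survey_dataset(data, covariates = attr(template, "covariates"),
                 validate = FALSE)
}

#' Read survey microdata from a delimited file
#'
#' Reads a CSV/TSV file with a header row, renames columns according to a
#' role mapping, coerces types, and drops records that violate the hard
#' invariants (non-positive weight, non-finite wealth score, non-positive
#' waist). Drop counts are recorded in the `drop_log` attribute of the result
#' and available via [drop_log()].
#'
#' @param path Path to a delimited text file (`.tsv`/`.tab` are read as
#'   tab-separated, anything else as comma-separated).
#' @param schema Named character vector mapping roles to column names in the
#'   file. Required roles: `sex`, `age`, `waist`, `wealth`, `weight`.
#'   Optional: `id`, `year`, `psu`, `stratum`, `pregnant`.
#' @param covariates Character vector of additional columns to carry along as
#'   categorical covariates, or a named list of role -> column with declared
#'   levels. `NULL` keeps none.
#'
#' @return A [survey_dataset()] with attribute `drop_log` (named integer
#'   vector).
#' @export
read_survey_table <- function(path, schema, covariates = NULL) {
  required_roles <- c("sex", "age", "waist", "wealth", "weight")
  miss <- setdiff(required_roles, names(schema))
  if (length(miss) > 0L) {
    rlang::abort(paste0("schema is missing required role(s): ",
                        paste(miss, collapse = ", ")),
                 class = "ineq_config_error")
  }
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  all_roles <- c(required_roles, intersect(
    c("id", "year", "psu", "stratum", "pregnant"), names(schema)))
  for (role in all_roles) {
    col <- schema[[role]]
    if (!col %in% names(raw)) {
      rlang::abort(paste0("input file is missing the '", role,
                          "' column ('", col, "')"),
                   class = "ineq_config_error")
    }
  }
  cov_cols <- if (is.list(covariates)) names(covariates) else covariates
  miss_cov <- setdiff(cov_cols, names(raw))
  if (length(miss_cov) > 0L) {
    rlang::abort(paste0("input file is missing covariate column(s): ",
                        paste(miss_cov, collapse = ", ")),
                 class = "ineq_config_error")
  }

  out <- tibble::tibble(
    person_id = if ("id" %in% all_roles) as.character(raw[[schema[["id"]]]])
                else as.character(seq_len(nrow(raw))),
    year = if ("year" %in% all_roles) as.character(raw[[schema[["year"]]]])
           else "pooled",
    sex = tolower(as.character(raw[[schema[["sex"]]]])),
    age_years = as.integer(raw[[schema[["age"]]]]),
    waist_cm = as.numeric(raw[[schema[["waist"]]]]),
    wealth_score = as.numeric(raw[[schema[["wealth"]]]]),
    weight = as.numeric(raw[[schema[["weight"]]]])
  )
  if ("psu" %in% all_roles) out$psu <- as.character(raw[[schema[["psu"]]]])
  if ("stratum" %in% all_roles) {
    out$stratum <- as.character(raw[[schema[["stratum"]]]])
  }
  if ("pregnant" %in% all_roles) {
    out$pregnant <- as.logical(raw[[schema[["pregnant"]]]])
  }
  for (cc in cov_cols) out[[cc]] <- as.character(raw[[cc]])

  bad_weight <- !is.finite(out$weight) | out$weight <= 0
  bad_wealth <- !bad_weight & !is.finite(out$wealth_score)
  bad_waist <- !bad_weight & !bad_wealth & !is.na(out$waist_cm) &
    (!is.finite(out$waist_cm) | out$waist_cm <= 0)
  drop_log <- c(
    nonpositive_weight = sum(bad_weight),
    nonfinite_wealth = sum(bad_wealth),
    invalid_waist = sum(bad_waist)
  )
  keep <- !(bad_weight | bad_wealth | bad_waist)
  if (!any(keep)) {
    rlang::abort("no valid records after applying input invariants",
                 class = "ineq_data_error")
  }
  if (sum(drop_log) > 0L) {
    rlang::inform(paste0("read_survey_table: dropped ", sum(drop_log),
                         " invalid record(s)"))
  }
  cov_schema <- if (is.list(covariates)) covariates else NULL
  ds <- survey_dataset(out[keep, , drop = FALSE], covariates = cov_schema)
  attr(ds, "drop_log") <- drop_log
  ds
}

#' Dropped-record counts from ingestion
#'
#' @param dataset A dataset returned by [read_survey_table()].
#' @return Named integer vector of drop counts by reason (zeros if the
#'   dataset was built in memory).
#' @export
drop_log <- function(dataset) {
  dl <- attr(dataset, "drop_log")
  if (is.null(dl)) {
    dl <- c(nonpositive_weight = 0L, nonfinite_wealth = 0L, invalid_waist = 0L)
  }
  dl
}

#' Write a survey dataset to CSV
#'
#' Writes the canonical tidy table (one row per person, fixed column order:
#' identifiers, design columns, analysis variables, covariates) so that
#' `read_survey_table()` on the result round-trips.
#'
#' @param dataset A [survey_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(dataset, path) {
  fixed <- intersect(
    c("person_id", "year", "psu", "stratum", "sex", "age_years", "pregnant",
      "waist_cm", "wealth_score", "weight"),
    names(dataset)
  )
  other <- setdiff(names(dataset), fixed)
  out <- as.data.frame(dataset)[, c(fixed, other), drop = FALSE]
  for (j in seq_along(out)) if (is.factor(out[[j]])) {
    out[[j]] <- as.character(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Apply eligibility criteria
#'
#' Filters a dataset to the analysis population, counting exclusions in a
#' fixed order: minimum age first, then pregnancy, then missing waist
#' circumference (each record is counted once, under the first rule that
#' excludes it). The pregnancy rule is inert when the dataset carries no
#' `pregnant` column.
#'
#' @param dataset A [survey_dataset()].
#' @param min_age Minimum age in whole years (the boundary age is eligible).
#' @param require_waist Exclude records with missing waist circumference.
#' @param exclude_pregnant Exclude records flagged pregnant.
#'
#' @return The filtered `survey_dataset` with attribute `exclusions`, a named
#'   integer vector `c(age, pregnancy, missing_waist)`; see [exclusion_counts()].
#' @export
apply_eligibility <- function(dataset, min_age = 18L, require_waist = TRUE,
                              exclude_pregnant = TRUE) {
  if (nrow(dataset) == 0L) {
    rlang::abort("dataset is empty", class = "ineq_data_error")
  }
  excl_age <- dataset$age_years < min_age
  preg <- if (exclude_pregnant && "pregnant" %in% names(dataset)) {
    !excl_age & !is.na(dataset$pregnant) & dataset$pregnant
  } else {
    rep(FALSE, nrow(dataset))
  }
  no_waist <- if (require_waist) {
    !excl_age & !preg & is.na(dataset$waist_cm)
  } else {
    rep(FALSE, nrow(dataset))
  }
  counts <- c(age = sum(excl_age), pregnancy = sum(preg),
              missing_waist = sum(no_waist))
  keep <- !(excl_age | preg | no_waist)
  if (!any(keep)) {
    rlang::abort("all records excluded by eligibility criteria",
                 class = "ineq_data_error")
  }
  out <- restore_survey(dataset[keep, , drop = FALSE], dataset)
  attr(out, "exclusions") <- counts
  out
}

#' Exclusion counts recorded by [apply_eligibility()]
#'
#' @param dataset A dataset returned by [apply_eligibility()].
#' @return Named integer vector in fixed order (age, pregnancy, missing_waist).
#' @export
exclusion_counts <- function(dataset) {
  ex <- attr(dataset, "exclusions")
  if (is.null(ex)) ex <- c(age = 0L, pregnancy = 0L, missing_waist = 0L)
  ex
}

#' Pool survey rounds
#'
#' Concatenates several survey datasets (e.g. consecutive annual rounds) into
#' one. Under `weight_policy = "per_year_normalized"` each year's expansion
#' factors are rescaled so that the year's weight total equals its unweighted
#' record count; each round then contributes to pooled estimates in
#' proportion to its sample size rather than its expansion total. Under
#' `"as_is"` weights are left untouched.
#'
#' @param datasets List of [survey_dataset()] objects with identical
#'   covariate schemas.
#' @param weight_policy `"per_year_normalized"` (default) or `"as_is"`.
#' @return A pooled `survey_dataset`.
#' @export
pool_datasets <- function(datasets,
                          weight_policy = c("per_year_normalized", "as_is")) {
  weight_policy <- match.arg(weight_policy)
  if (!is.list(datasets) || length(datasets) < 1L) {
    rlang::abort("datasets must be a non-empty list", class = "ineq_config_error")
  }
  schemas <- lapply(datasets, covariate_schema)
  for (i in seq_along(schemas)[-1]) {
    if (!identical(schemas[[i]], schemas[[1]])) {
      rlang::abort("datasets have incompatible covariate schemas",
                   class = "ineq_config_error")
    }
  }
  pooled <- dplyr::bind_rows(lapply(datasets, tibble::as_tibble))
  if (weight_policy == "per_year_normalized") {
    pooled <- pooled |>
      dplyr::group_by(.data$year) |>
      dplyr::mutate(weight = .data$weight * dplyr::n() / sum(.data$weight)) |>
      dplyr::ungroup()
  }
  survey_dataset(pooled, covariates = schemas[[1]])
}

#' Assign weighted wealth quintiles
#'
#' Orders records by `wealth_score` and cuts the cumulative normalized weight
#' at fractions 0.2, 0.4, 0.6, 0.8. Each record is assigned to the quintile
#' containing its weight midpoint (its fractional rank); a record whose mass
#' straddles a boundary therefore goes to the lower quintile exactly when no
#' strict majority of its mass lies above the cut. Records tied on
#' `wealth_score` share one rank and hence one quintile. The assignment
#' depends on wealth only through its ordering, so it is invariant to
#' strictly monotone transforms of the score.
#'
#' @param dataset A [survey_dataset()].
#' @return Factor of length `nrow(dataset)` with levels `Q1` (poorest) ...
#'   `Q5` (richest), aligned with the dataset rows.
#' @export
assign_wealth_quintiles <- function(dataset) {
  if (anyNA(dataset$wealth_score)) {
    rlang::abort("wealth_score must be present for all records",
                 class = "ineq_data_error")
  }
  if (length(unique(dataset$wealth_score)) < 5L) {
    rlang::warn("fewer than 5 distinct wealth values: quintiles are degenerate")
  }
  r <- fractional_rank(dataset$wealth_score, dataset$weight)
  q <- pmin(pmax(ceiling(r * 5), 1L), 5L)
  factor(paste0("Q", q), levels = paste0("Q", 1:5))
}
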