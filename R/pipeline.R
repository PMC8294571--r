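#' Configuration for an end-to-end inequality analysis
#'
#' Collects every choice the full analysis needs: input data (either an
#' in-memory [survey_dataset()], or file paths plus a role schema for
#' [read_survey_table()]), the abdominal-obesity criterion, eligibility
#' flags, the pooling weight policy, whether ranks are computed on the
#' pooled sample or within sex, the standard-error method, the covariate
#' list with reference levels, and the output directory.
#'
#' @param input A `survey_dataset`, a list of them (pooled in order), or a
#'   character vector of file paths.
#' @param schema Role mapping for [read_survey_table()] (when `input` is
#'   paths).
#' @param covariates Character vector of covariate columns for descriptives
#'   and decomposition.
#' @param refs Optional named vector of reference levels.
#' @param criterion `"IDF"`, `"ATPIII"` or `"LASO"`.
#' @param extra_criteria Additional criteria for the prevalence
#'   sub-analysis (default: the other two systems).
#' @param min_age,require_waist,exclude_pregnant Eligibility settings.
#' @param weight_policy Pooling policy, see [pool_datasets()].
#' @param rank_scope `"within_sex"` (ranks recomputed inside each sex
#'   stratum; default) or `"pooled"`.
#' @param se_method Standard-error method for the indices.
#' @param ci_method Confidence-interval method for prevalences.
#' @param age_breaks Analysis age bands (lower bounds) used for
#'   age-standardization against the WHO world standard.
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given the inputs).
#' @return A `run_config` list.
#' @export
run_config <- function(input, schema = NULL,
                       covariates = c("age_group", "marital_status",
                                      "education", "wealth_quintile",
                                      "region", "area", "altitude",
                                      "chronic_disease", "smoker"),
                       refs = NULL,
                       criterion = c("IDF", "ATPIII", "LASO"),
                       extra_criteria = NULL,
                       min_age = 18L, require_waist = TRUE,
                       exclude_pregnant = TRUE,
                       weight_policy = c("per_year_normalized", "as_is"),
                       rank_scope = c("within_sex", "pooled"),
                       se_method = c("convenient_regression",
                                     "cluster_robust"),
                       ci_method = c("taylor", "wilson"),
                       age_breaks = c(18L, 30L, 60L),
                       out_dir = "results", seed = 1L) {
  criterion <- match.arg(criterion)
  if (is.null(extra_criteria)) {
    extra_criteria <- setdiff(c("IDF", "ATPIII", "LASO"), criterion)
  }
  structure(list(
    input = input, schema = schema, covariates = covariates, refs = refs,
    criterion = criterion, extra_criteria = extra_criteria,
    min_age = min_age, require_waist = require_waist,
    exclude_pregnant = exclude_pregnant,
    weight_policy = match.arg(weight_policy),
    rank_scope = match.arg(rank_scope),
    se_method = match.arg(se_method), ci_method = match.arg(ci_method),
    age_breaks = age_breaks, out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Reads a configuration file whose top-level keys are the arguments of
#' [run_config()] (`input` as file path(s), `schema` as a role -> column
#' map, plus any of the option fields) and builds the `run_config`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
run_config_from_file <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
                 class = "ineq_config_error")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    rlang::abort(paste0("unknown config field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "ineq_config_error")
  }
  for (f in c("schema", "refs")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(run_config, raw)
}

# order-invariant fingerprint of the configuration (not the data)
config_hash <- function(config) {
  fields <- config[setdiff(names(config), c("input", "schema"))]
  txt <- jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA,
                          null = "null")
  # 31-bit polynomial rolling hash over the serialized config
  h <- 7
  for (code in utf8ToInt(as.character(txt))) {
    h <- (h * 131 + code) %% 2147483647
  }
  sprintf("%08x", h)
}

load_config_input <- function(config) {
  inp <- config$input
  if (inherits(inp, "survey_dataset")) return(list(inp))
  if (is.character(inp)) {
    return(lapply(inp, read_survey_table, schema = config$schema))
  }
  if (is.list(inp)) return(inp)
  rlang::abort("unsupported input specification", class = "ineq_config_error")
}

analyse_sex_group <- function(df, template, config) {
  ds <- restore_survey(df, template)
  ro <- ranked_outcome(ds$abdominal_obesity, ds$wealth_score, ds$weight,
                       bounds = c(0, 1),
                       cluster = if ("psu" %in% names(ds)) ds$psu else NULL)
  eci <- erreygers_index(ro, se_method = config$se_method)
  curve <- concentration_curve(ro)
  dec <- decompose_eci(ds, "abdominal_obesity",
                       setdiff(config$covariates, "sex"),
                       refs = config$refs, se_method = config$se_method)
  list(eci = eci, curve = curve, decomposition = dec)
}

#' Run the full inequality analysis
#'
#' Executes the complete pipeline on a conforming dataset: ingestion,
#' eligibility filtering, pooling of survey rounds, weighted wealth-quintile
#' assignment, abdominal-obesity classification under the configured
#' criterion (plus the alternative criteria for the prevalence
#' sub-analysis), age-standardized and covariate-stratified prevalence
#' tables, per-sex concentration curves, Erreygers indices, and the ECI
#' decomposition. All tables are written as CSV under `config$out_dir`
#' together with a JSON run manifest (config hash, drop and exclusion
#' counts, index estimates); the run is deterministic given inputs and
#' configuration. Any stage failure aborts the run and removes partial
#' outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `prevalence`, `prevalence_by_criterion`, `standardized`, per-sex `eci`,
#'   `curves`, `decompositions`, `manifest`).
#' @export
run_analysis <- function(config) {
  out_dir <- config$out_dir
  dir_existed <- dir.exists(out_dir)
  written <- character()
  stage <- "setup"
  result <- tryCatch({
    stage <- "ingest"
    datasets <- load_config_input(config)
    drops <- lapply(datasets, drop_log)

    stage <- "eligibility"
    datasets <- lapply(datasets, apply_eligibility,
                       min_age = config$min_age,
                       require_waist = config$require_waist,
                       exclude_pregnant = config$exclude_pregnant)
    exclusions <- lapply(datasets, exclusion_counts)

    stage <- "pooling"
    pooled <- pool_datasets(datasets, weight_policy = config$weight_policy)

    stage <- "quintiles"
    pooled$wealth_quintile <- assign_wealth_quintiles(pooled)
    schema <- c(covariate_schema(pooled),
                list(wealth_quintile = paste0("Q", 1:5)))
    pooled <- survey_dataset(tibble::as_tibble(pooled), covariates = schema)

    stage <- "classification"
    pooled$abdominal_obesity <- classify_abdominal_obesity(
      pooled$waist_cm, pooled$sex, config$criterion)

    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    emit <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(as.data.frame(df), path, row.names = FALSE)
      written <<- c(written, path)
      path
    }

    stage <- "descriptives"
    by_cov <- intersect(config$covariates, names(pooled))
    prev <- dplyr::bind_rows(lapply(by_cov, function(cv) {
      tab <- weighted_prevalence(pooled, "abdominal_obesity",
                                 by = c("sex", cv),
                                 ci_method = config$ci_method)
      tab$variable <- cv
      tab
    }))
    emit(prev, "prevalence_by_group.csv")
    waist_tab <- weighted_mean_se(pooled, "waist_cm", by = "sex")
    emit(waist_tab, "waist_mean_by_sex.csv")

    prev_crit <- dplyr::bind_rows(lapply(
      c(config$criterion, config$extra_criteria), function(cr) {
        y <- classify_abdominal_obesity(pooled$waist_cm, pooled$sex, cr)
        tmp <- pooled
        tmp$ao_tmp <- y
        tab <- weighted_prevalence(restore_survey(tmp, pooled), "ao_tmp",
                                   by = "sex", ci_method = config$ci_method)
        tab$criterion <- cr
        tab
      }))
    emit(prev_crit, "prevalence_by_criterion.csv")

    stage <- "age_standardization"
    std <- who_standard_population(breaks = config$age_breaks)
    band <- findInterval(pooled$age_years, config$age_breaks)
    band <- factor(config$age_breaks[pmax(band, 1L)],
                   levels = config$age_breaks)
    std_rows <- lapply(c("male", "female"), function(sx) {
      idx <- pooled$sex == sx & !is.na(pooled$abdominal_obesity)
      est <- vapply(split(seq_len(nrow(pooled))[idx], band[idx]),
                    function(ii) {
                      sum(pooled$weight[ii] * pooled$abdominal_obesity[ii]) /
                        sum(pooled$weight[ii])
                    }, numeric(1))
      tibble::tibble(sex = sx,
                     standardized_prevalence = age_standardize(est, std))
    })
    standardized <- dplyr::bind_rows(std_rows)
    emit(standardized, "age_standardized_prevalence.csv")

    stage <- "inequality"
    groups <- if (config$rank_scope == "within_sex") {
      split(seq_len(nrow(pooled)), pooled$sex)
    } else {
      list(pooled = seq_len(nrow(pooled)))
    }
    per_group <- lapply(groups, function(idx) {
      analyse_sex_group(tibble::as_tibble(pooled)[idx, , drop = FALSE],
                        pooled, config)
    })
    eci_tab <- dplyr::bind_rows(lapply(names(per_group), function(g) {
      e <- per_group[[g]]$eci
      tibble::tibble(group = g, index = "ECI", value = e$value, se = e$se,
                     n = e$n, mu = e$mu, se_method = e$se_method)
    }))
    emit(eci_tab, "concentration_indices.csv")
    for (g in names(per_group)) {
      emit(per_group[[g]]$curve, paste0("concentration_curve_", g, ".csv"))
      dec <- per_group[[g]]$decomposition
      dec_tab <- dec$rows
      dec_tab <- dplyr::bind_rows(
        dec_tab,
        tibble::tibble(variable = "(residual)", level = "(residual)",
                       contribution = dec$residual),
        tibble::tibble(variable = "(total_eci)", level = "(total_eci)",
                       contribution = dec$total_eci)
      )
      emit(dec_tab, paste0("decomposition_", g, ".csv"))
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("ineqdecomp")),
      config_hash = config_hash(config),
      seed = config$seed,
      criterion = config$criterion,
      weight_policy = config$weight_policy,
      rank_scope = config$rank_scope,
      se_method = config$se_method,
      ci_method = config$ci_method,
      n_input = vapply(drops, function(x) NA_integer_, integer(1)),
      drop_counts = drops,
      exclusion_counts = exclusions,
      n_analysis = nrow(pooled),
      eci = stats::setNames(eci_tab$value, eci_tab$group),
      outputs = basename(written)
    )
    manifest$n_input <- NULL
    manifest_path <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, manifest_path)

    list(dataset = pooled, prevalence = prev,
         prevalence_by_criterion = prev_crit, standardized = standardized,
         waist = waist_tab,
         eci = lapply(per_group, `[[`, "eci"),
         curves = lapply(per_group, `[[`, "curve"),
         decompositions = lapply(per_group, `[[`, "decomposition"),
         manifest = manifest)
  }, error = function(cond) {
    unlink(written)
    if (!dir_existed && dir.exists(out_dir) &&
        length(list.files(out_dir, all.files = TRUE, no.. = TRUE)) == 0L) {
      unlink(out_dir, recursive = TRUE)
    }
    rlang::abort(paste0("pipeline failed at stage '", stage, "': ",
                        conditionMessage(cond)),
                 class = "ineq_pipeline_error", parent = cond)
  })
  invisible(result)
}
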