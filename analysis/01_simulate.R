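#!/usr/bin/env Rscript
# Generate two synthetic survey rounds emulating the pooled 2018-2019
# ENDES structure (wealth-graded covariates, expansion weights, waist
# circumference, a pregnancy flag), and write them as canonical CSVs.
# Sizes are kept at 15,000 respondents per round: large enough for stable
# indices, small enough to re-run in seconds.

library(ineqdecomp)

out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (spec in list(list(year = "2018", seed = 2018L),
                  list(year = "2019", seed = 2019L))) {
  design <- synthetic_design(n = 15000L, seed = spec$seed,
                             year_label = spec$year)
  pop <- generate_population(design)
  path <- file.path(out_dir, paste0("endes_like_", spec$year, ".csv"))
  write_survey_table(pop, path)
  cat(sprintf("%s: %d records, weighted AO prevalence %.3f -> %s\n",
              spec$year, nrow(pop),
              weighted.mean(pop$abdominal_obesity, pop$weight), path))
}
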