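#!/usr/bin/env Rscript

# Step 1: generate the calibrated synthetic hospital survey.
#
# Draws n hospital-level records (eight organizational-factor scores on the
# 0-10 scale plus the patient-safety-error proportion) from the Gaussian
# copula fitted to the packaged calibration, and writes them to
# results/survey.csv. All later steps read that file.

suppressPackageStartupMessages(library(safetybbn))

seed <- 2026L
out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cal <- read_calibration()
print(cal)

survey <- generate_survey(cal$marginals, cal$correlation, n = cal$n,
                          seed = seed)
write_survey_csv(survey, file.path(out_dir, "survey.csv"))

cat(sprintf("\nwrote %d records to %s\n", nrow(survey),
            file.path(out_dir, "survey.csv")))
cat("\nsample moments vs calibration targets:\n")
print(data.frame(
  variable = cal$marginals$name,
  target_mean = cal$marginals$mean,
  sample_mean = round(colMeans(survey)[cal$marginals$name], 3),
  target_sd = cal$marginals$sd,
  sample_sd = round(apply(survey, 2, stats::sd)[cal$marginals$name], 3),
  row.names = NULL))
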