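#!/usr/bin/env Rscript

# Step 2: discretize the survey into 2- and 3-state versions.
#
# Fits uniform-width schemes on the observed ranges of results/survey.csv
# and writes them to results/scheme_k2.json and results/scheme_k3.json,
# printing the state occupancies so sparse cells are visible before
# structure learning.

suppressPackageStartupMessages(library(safetybbn))

survey <- read_survey_csv("results/survey.csv")

for (k in c(2L, 3L)) {
  scheme <- fit_uniform_width(survey, k)
  disc <- apply_scheme(scheme, survey)
  scheme_to_json(scheme, sprintf("results/scheme_k%d.json", k))
  cat(sprintf("\n== %d-state scheme ==\n", k))
  occ <- t(apply(disc, 2, tabulate, nbins = k))
  colnames(occ) <- paste0("s", seq_len(k))
  print(occ)
}
cat("\nwrote results/scheme_k2.json and results/scheme_k3.json\n")
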