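#!/usr/bin/env Rscript

# Step 4: sensitivity analysis and cross-validated accuracy.
#
# Cross-validates every (number of states, learner) cell on
# results/survey.csv, writes the grid to results/model_comparison.csv, then
# re-validates the working model (3 states, PC, 6 folds) and writes its
# confusion matrix to results/confusion.csv.

suppressPackageStartupMessages(library(safetybbn))

seed <- 2026L
survey <- read_survey_csv("results/survey.csv")

grid <- compare_models(
  survey,
  configs = list(pc = learner_config("pc"),
                 gtt = learner_config("gtt"),
                 bs = learner_config("bs")),
  schemes = c(2L, 3L), k_folds = 6, seed = seed)
utils::write.csv(grid, "results/model_comparison.csv", row.names = FALSE)
cat("== accuracy grid (6-fold CV) ==\n")
print(grid)

disc <- apply_scheme(fit_uniform_width(survey, 3L), survey)
cm <- kfold_validate(disc, learner_config("pc"),
                     target = "patient_safety_errors", k_folds = 6,
                     seed = seed)
utils::write.csv(as.data.frame(unclass(cm)), "results/confusion.csv")
cat("\n== working model (3 states, PC) ==\n")
print(cm)
cat(sprintf("majority-class baseline = %.4f\n",
            majority_baseline(disc, "patient_safety_errors")))
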