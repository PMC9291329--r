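#!/usr/bin/env Rscript

# Step 3: learn the network structure with all three algorithms.
#
# On the 3-state discretization of results/survey.csv, runs the
# constraint-based PC learner (G-squared tests at alpha = 0.05) and the two
# score-based learners (greedy thickening/thinning and restarted hill
# climbing, both under BDeu with ess = 1), then writes each DAG as JSON and
# Graphviz DOT under results/.

suppressPackageStartupMessages(library(safetybbn))

seed <- 2026L
survey <- read_survey_csv("results/survey.csv")
disc <- apply_scheme(fit_uniform_width(survey, 3L), survey)

dags <- list(
  pc = learn_pc(disc, alpha = 0.05),
  gtt = learn_gtt(disc, ess = 1),
  bs = learn_bayesian_search(disc, restarts = 20, ess = 1, seed = seed)
)

for (nm in names(dags)) {
  g <- dags[[nm]]
  dag_to_json(g, sprintf("results/dag_%s.json", nm))
  dag_to_dot(g, sprintf("results/dag_%s.dot", nm))
  cat(sprintf("\n== %s: %d arcs (BDeu score %.2f) ==\n", nm, n_edges(g),
              bdeu_score(g, disc)))
  print(edge_list(g))
}

cat("\narcs into/out of the target by learner:\n")
tgt <- "patient_safety_errors"
for (nm in names(dags)) {
  g <- dags[[nm]]
  cat(sprintf("  %s: parents {%s}, children {%s}\n", nm,
              paste(parents(g, tgt), collapse = ", "),
              paste(children(g, tgt), collapse = ", ")))
}
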