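#' Build and validate a pipeline configuration
#'
#' Collects everything one end-to-end run needs: a data source (a packaged
#' or user calibration for synthetic generation, or a CSV of real records),
#' the number of discretization states, the structure learner, the
#' cross-validation folds, the seed and the output directory. Validation
#' happens before any compute.
#'
#' @param calibration Path to a YAML calibration (default: the packaged NHS
#'   staff survey calibration) used when `csv` is NULL.
#' @param csv Optional path to a survey CSV; overrides synthetic generation.
#' @param n Number of synthetic records (default: the calibration's n).
#' @param states Discretization states per variable, 2 or 3.
#' @param algorithm Structure learner: "pc", "gtt" or "bs".
#' @param learner_params Extra parameters for the learner.
#' @param k_folds Cross-validation folds (>= 2).
#' @param seed Integer seed driving generation, shuffling and any
#'   stochastic learner.
#' @param out_dir Output directory for run artifacts (NULL: no files
#'   written).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(calibration = default_calibration_path(),
                            csv = NULL, n = NULL, states = 3,
                            algorithm = c("pc", "gtt", "bs"),
                            learner_params = list(), k_folds = 6, seed = 1,
                            out_dir = NULL) {
  algorithm <- match.arg(algorithm)
  if (!states %in% c(2, 3)) stop("field 'states' must be 2 or 3")
  if (!is.numeric(k_folds) || k_folds < 2) {
    stop("field 'k_folds' must be an integer >= 2")
  }
  if (!is.numeric(seed) || length(seed) != 1) {
    stop("field 'seed' must be a single integer")
  }
  if (!is.null(csv) && !file.exists(csv)) {
    stop("field 'csv': file not found: ", csv)
  }
  structure(list(calibration = calibration, csv = csv, n = n,
                 states = as.integer(states), algorithm = algorithm,
                 learner_params = learner_params,
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes generate/load -> discretize -> learn structure -> fit CPTs ->
#' cross-validate -> scenario analysis, persisting CSV/JSON/DOT artifacts
#' to the configured output directory. Every stage is deterministic given
#' the config seed; downstream errors carry the failing stage's name.
#'
#' @param config A `pipeline_config`.
#' @return A `run_report` list: `survey`, `scheme`, `dag`, `net`,
#'   `confusion`, `accuracy`, `baseline`, `backward`, `impact`, `rankings`
#'   (vulnerability and resilience), `rank_correlation`, `warnings`, and a
#'   `config` echo with per-stage timings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings <- character(0)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warnings <<- c(warnings, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  cal <- stage("calibrate", read_calibration(config$calibration))
  target <- cal$target
  survey <- stage("data", {
    if (is.null(config$csv)) {
      n <- if (is.null(config$n)) cal$n else config$n
      generate_survey(cal$marginals, cal$correlation, n = n,
                      seed = config$seed)
    } else {
      read_survey_csv(config$csv, target = target)
    }
  })
  scheme <- stage("discretize", fit_uniform_width(survey, config$states))
  disc <- stage("discretize", apply_scheme(scheme, survey))
  lc <- do.call(learner_config,
                c(list(algorithm = config$algorithm), config$learner_params))
  dag <- stage("learn", learn_structure(disc, lc, seed = config$seed))
  net <- stage("fit", fit_cpts(dag, disc, alpha = 1))
  cm <- stage("validate",
              kfold_validate(disc, lc, target = target,
                             k_folds = config$k_folds, seed = config$seed))
  backward <- stage("analyze", {
    list(low = backward_propagation(net, target, 1L),
         high = backward_propagation(net, target, cardinalities(disc)[[target]]))
  })
  impact <- stage("analyze", impact_assessment(net, target))
  vuln <- stage("analyze", rank_factors(impact, "vulnerability"))
  resi <- stage("analyze", rank_factors(impact, "resilience"))
  rc <- stage("analyze", spearman_rank_corr(vuln, resi))

  report <- list(survey = survey, scheme = scheme, dag = dag, net = net,
                 confusion = cm, accuracy = accuracy(cm),
                 baseline = majority_baseline(disc, target),
                 backward = backward, impact = impact,
                 rankings = list(vulnerability = vuln, resilience = resi),
                 rank_correlation = rc, warnings = warnings,
                 config = config, timings = timings)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_run_artifacts(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("BBN pipeline run (", x$config$algorithm, ", ", x$config$states,
      " states, ", x$config$k_folds, " folds, seed ", x$config$seed, ")\n",
      sep = "")
  cat(sprintf("  records: %d   arcs: %d\n", nrow(x$survey), n_edges(x$dag)))
  cat(sprintf("  CV accuracy: %.3f (majority baseline %.3f)\n",
              x$accuracy, x$baseline))
  cat(sprintf("  prior P(worst error state): %.3f\n",
              attr(x$impact, "baseline")))
  cat(sprintf("  vulnerability #1: %s   resilience #1: %s\n",
              x$rankings$vulnerability$factor[
                which.min(x$rankings$vulnerability$rank)],
              x$rankings$resilience$factor[
                which.min(x$rankings$resilience$rank)]))
  cat(sprintf("  rank correlation (vulnerability vs resilience): %.4f\n",
              x$rank_correlation))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Persist all artifacts of a pipeline run
#'
#' Writes the survey CSV, discretization scheme JSON, DAG JSON and DOT,
#' network JSON, confusion matrix CSV, impact and ranking CSVs, and a
#' report JSON (config echo, accuracy, rank correlation, warnings, seed,
#' timings) into `dir`.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_survey_csv(report$survey, fp("survey.csv"))
  scheme_to_json(report$scheme, fp("scheme.json"))
  dag_to_json(report$dag, fp("dag.json"))
  dag_to_dot(report$dag, fp("dag.dot"))
  net_to_json(report$net, fp("net.json"))
  utils::write.csv(as.data.frame(unclass(report$confusion)),
                   fp("confusion.csv"))
  utils::write.csv(cbind(report$impact,
                         baseline = attr(report$impact, "baseline")),
                   fp("impact.csv"), row.names = FALSE)
  rk <- merge(report$rankings$vulnerability, report$rankings$resilience,
              by = "factor", suffixes = c("_vulnerability", "_resilience"))
  utils::write.csv(rk, fp("rankings.csv"), row.names = FALSE)
  cfg <- report$config
  jsonlite::write_json(
    list(config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
         accuracy = report$accuracy, baseline = report$baseline,
         prior_worst = attr(report$impact, "baseline"),
         rank_correlation = report$rank_correlation,
         warnings = report$warnings, timings = as.list(report$timings)),
    fp("report.json"), auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}
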