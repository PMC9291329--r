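#' k-fold cross-validated prediction of the target state
#'
#' Shuffles the records into `k_folds` near-equal parts (sizes differing by
#' at most one), learns the structure once on the full data, refits CPT
#' parameters on each training split, and predicts every held-out record's
#' target state by MAP inference with all other variables as evidence. Each
#' record is tested exactly once; counts accumulate into a confusion
#' matrix. Set `refit_structure = TRUE` to relearn the structure inside
#' each fold instead.
#'
#' @param data A `discrete_data` object.
#' @param learner_config Learner specification, e.g.
#'   `learner_config("pc", alpha = 0.05)`; see [learner_config()].
#' @param target Target variable label.
#' @param k_folds Number of folds (>= 2, <= n).
#' @param seed Integer seed for the shuffle (and any stochastic learner).
#' @param alpha CPT pseudocount used when refitting parameters.
#' @param refit_structure Relearn structure per fold (default FALSE).
#' @return A `confusion_matrix`: k x k integer matrix (rows = actual,
#'   columns = predicted) with attributes `n`, `fallbacks` and `dag` (the
#'   full-data structure).
#' @export
kfold_validate <- function(data, learner_config, target, k_folds = 6,
                           seed = 1, alpha = 1, refit_structure = FALSE) {
  n <- nrow(data)
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (k_folds > n) stop("k_folds cannot exceed the number of records")
  if (!target %in% colnames(data)) stop("unknown target '", target, "'")
  folds <- withr::with_seed(seed, {
    sample(rep(seq_len(k_folds), length.out = n))
  })
  full_dag <- learn_structure(data, learner_config, seed = seed)
  kt <- cardinalities(data)[[target]]
  cm <- matrix(0L, kt, kt,
               dimnames = list(actual = paste0("s", seq_len(kt)),
                               predicted = paste0("s", seq_len(kt))))
  fallbacks <- 0L
  others <- setdiff(colnames(data), target)
  for (fold in seq_len(k_folds)) {
    train <- data[folds != fold, , drop = FALSE]
    train <- new_discrete_data(train, cardinalities(data))
    dag <- if (refit_structure) {
      learn_structure(train, learner_config, seed = seed + fold)
    } else {
      full_dag
    }
    net <- fit_cpts(dag, train, alpha = alpha)
    test_idx <- which(folds == fold)
    for (i in test_idx) {
      rec <- stats::setNames(as.integer(data[i, others]), others)
      pred <- predict_map(net, rec, target)
      fallbacks <- fallbacks + attr(pred, "fallbacks")
      cm[data[i, target], pred] <- cm[data[i, target], pred] + 1L
    }
  }
  structure(cm, class = c("confusion_matrix", "matrix"), n = n,
            fallbacks = fallbacks, dag = full_dag)
}

#' Specify a structure learner
#'
#' @param algorithm One of "pc", "gtt", "bs", or "fixed" (use a
#'   pre-specified DAG passed as `dag`).
#' @param ... Parameters forwarded to the learner ([learn_pc()],
#'   [learn_gtt()], [learn_bayesian_search()]), or `dag` for "fixed".
#' @return A `learner_config` list.
#' @export
learner_config <- function(algorithm = c("pc", "gtt", "bs", "fixed"), ...) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, params = list(...)),
            class = "learner_config")
}

#' @param data A `discrete_data` object.
#' @param config A `learner_config`.
#' @param seed Seed used by stochastic learners.
#' @rdname learner_config
#' @export
learn_structure <- function(data, config, seed = 1) {
  p <- config$params
  switch(config$algorithm,
    pc = do.call(learn_pc, c(list(data = data), p)),
    gtt = do.call(learn_gtt, c(list(data = data), p)),
    bs = do.call(learn_bayesian_search,
                 c(list(data = data),
                   if (is.null(p$seed)) list(seed = seed) else list(), p)),
    fixed = p$dag)
}

#' Prediction accuracy of a confusion matrix
#'
#' The fraction of correct predictions: trace / total record count.
#'
#' @param cm A `confusion_matrix` (any square count matrix works).
#' @return Accuracy in \[0, 1\].
#' @export
#' @examples
#' accuracy(matrix(c(300, 50, 41, 22), 2)) # 322 correct of 413
accuracy <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(as.matrix(cm))) / n
}

#' Majority-class baseline accuracy
#'
#' Accuracy achieved by always predicting the target's most frequent state.
#'
#' @param data A `discrete_data` object.
#' @param target Target variable label.
#' @return Baseline accuracy in \[0, 1\].
#' @export
majority_baseline <- function(data, target) {
  max(tabulate(data[, target], cardinalities(data)[[target]])) / nrow(data)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (n =", attr(x, "n"), "):\n")
  print(unclass(x)[, , drop = FALSE])
  cat(sprintf("accuracy = %.4f\n", accuracy(x)))
  invisible(x)
}

#' Compare learners across discretization schemes
#'
#' Runs an independent cross-validation for every (number of states,
#' algorithm) cell: the continuous table is discretized at each scheme and
#' each learner is validated on the result. Mirrors the sensitivity
#' analysis used to pick the working model.
#'
#' @param table A continuous `survey_table`.
#' @param configs Named list of `learner_config` objects.
#' @param schemes Integer vector of state counts (subset of 2:3).
#' @param target Target variable label.
#' @param k_folds Folds per validation.
#' @param seed Shuffle seed shared by all cells.
#' @return A data frame with columns `states`, `algorithm`, `accuracy`,
#'   with the argmax cell flagged in column `best`.
#' @export
compare_models <- function(table, configs, schemes = c(2L, 3L),
                           target = "patient_safety_errors", k_folds = 6,
                           seed = 1) {
  if (!length(configs) || !length(schemes)) {
    stop("configs and schemes must be non-empty")
  }
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, function(cf) cf$algorithm, character(1))
  }
  rows <- list()
  for (k in schemes) {
    disc <- apply_scheme(fit_uniform_width(table, k), table)
    for (nm in names(configs)) {
      cm <- kfold_validate(disc, configs[[nm]], target = target,
                           k_folds = k_folds, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        states = k, algorithm = nm, accuracy = accuracy(cm),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.max(out$accuracy)
  out
}
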