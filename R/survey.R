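#' Generate a synthetic hospital survey table
#'
#' Draws hospital-level records from a Gaussian copula: latent multivariate
#' normal vectors with correlation `spearman_to_latent_pearson(corr)` are
#' pushed through the normal CDF to uniforms and then through each
#' variable's normal(mean, sd) quantile function, clipped to the observed
#' \[low, high\] range. Because all maps are monotone, the sample Spearman
#' correlations converge to `corr` (clipping introduces boundary ties whose
#' effect is negligible at the calibrated sd/range ratios), and sample
#' means/SDs converge to the marginal targets.
#'
#' @param marginals Data frame of marginal summaries, one row per variable,
#'   with columns `name`, `mean`, `sd`, `low`, `high`, `scale_max` (as in a
#'   [read_calibration()] object).
#' @param corr Spearman correlation matrix over the same variables, positive
#'   definite (see [build_correlation_matrix()]).
#' @param n Number of records to draw (>= 2).
#' @param seed Integer seed; identical inputs give bit-identical tables.
#' @return A data frame of `n` rows, one numeric column per variable, of
#'   class `survey_table`.
#' @export
#' @examples
#' cal <- read_calibration()
#' tab <- generate_survey(cal$marginals, cal$correlation, n = 500, seed = 1)
#' colMeans(tab)
generate_survey <- function(marginals, corr, n, seed) {
  validate_marginals(marginals)
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("n must be a single integer >= 2")
  }
  n <- as.integer(n)
  labels <- marginals$name
  if (!identical(sort(labels), sort(colnames(corr)))) {
    stop("marginals and correlation matrix must cover the same variables")
  }
  corr <- corr[labels, labels]
  latent <- spearman_to_latent_pearson(corr)
  diag(latent) <- 1
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    stop("correlation matrix is not positive definite; ",
         "repair it with repair_correlation() first")
  }
  z <- withr::with_seed(seed,
    MASS::mvrnorm(n, mu = rep(0, length(labels)), Sigma = latent))
  u <- stats::pnorm(z)
  out <- vapply(seq_along(labels), function(j) {
    m <- marginals[j, ]
    pmin(pmax(stats::qnorm(u[, j], mean = m$mean, sd = m$sd), m$low), m$high)
  }, numeric(n))
  colnames(out) <- labels
  as_survey_table(as.data.frame(out))
}

#' Validate and tag a survey table
#'
#' Checks the `survey_table` contract: all values numeric and non-missing,
#' factor scores within \[0, 10\], the target proportion within \[0, 1\],
#' at least two records. Violations are reported with row/column
#' coordinates.
#'
#' @param x Data frame of survey records.
#' @param target Name of the outcome column (proportion on \[0, 1\]); every
#'   other column is treated as a 0-10 factor score.
#' @return `x` with class `survey_table` prepended.
#' @export
as_survey_table <- function(x, target = "patient_safety_errors") {
  if (!is.data.frame(x)) stop("a survey table must be a data frame")
  if (nrow(x) < 2) stop("a survey table needs at least 2 records")
  for (j in names(x)) {
    col <- x[[j]]
    if (!is.numeric(col)) stop("column '", j, "' is not numeric")
    if (anyNA(col)) {
      stop("missing value at row ", which(is.na(col))[1], ", column '", j, "'")
    }
    hi <- if (identical(j, target)) 1 else 10
    bad <- which(col < 0 | col > hi)
    if (length(bad)) {
      stop("value ", col[bad[1]], " out of [0, ", hi, "] at row ", bad[1],
           ", column '", j, "'")
    }
  }
  class(x) <- unique(c("survey_table", class(x)))
  x
}

#' Read / write survey tables as CSV
#'
#' Plain comma-separated files with a header row of variable names, '.'
#' decimal separator, UTF-8. Reading validates the [as_survey_table()]
#' contract and reports offending cells by row and column.
#'
#' @param path File path.
#' @param target Name of the outcome column.
#' @return `read_survey_csv()` returns a `survey_table`;
#'   `write_survey_csv()` returns `path` invisibly.
#' @export
read_survey_csv <- function(path, target = "patient_safety_errors") {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  for (j in names(raw)) {
    if (is.character(raw[[j]])) {
      num <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(is.na(num) & !is.na(raw[[j]]) & nzchar(trimws(raw[[j]])))
      if (length(bad)) {
        stop("non-numeric cell '", raw[[j]][bad[1]], "' at row ", bad[1],
             ", column '", j, "'")
      }
      raw[[j]] <- num
    }
  }
  as_survey_table(raw, target = target)
}

#' @param x A `survey_table`.
#' @rdname read_survey_csv
#' @export
write_survey_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
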