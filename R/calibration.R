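#' Read a survey calibration from a YAML file
#'
#' A calibration bundles everything the synthetic survey generator needs:
#' per-variable marginal summaries (mean, SD, observed low/high, scale
#' maximum) and the Spearman rank-correlation structure (inter-factor block
#' plus factor-target column). The packaged default encodes hospital-level
#' aggregates of the UK NHS staff survey: eight organizational factor scores
#' on a 0-10 scale and the proportion of staff reporting patient-safety
#' errors on \[0, 1\], over 413 hospitals.
#'
#' @param path Path to a YAML calibration file. Defaults to the packaged
#'   NHS staff survey calibration.
#' @return An object of class `survey_calibration`: a list with elements
#'   `marginals` (a data frame, one row per variable), `correlation` (the
#'   assembled 9x9 Spearman matrix, see [build_correlation_matrix()]),
#'   `target` (name of the outcome variable) and `n` (the study sample size).
#' @export
#' @examples
#' cal <- read_calibration()
#' cal$marginals$mean
read_calibration <- function(path = default_calibration_path()) {
  raw <- yaml::read_yaml(path)
  marg <- do.call(rbind, lapply(raw$marginals, function(m) {
    data.frame(name = m$name, mean = m$mean, sd = m$sd, low = m$low,
               high = m$high, scale_max = m$scale_max,
               stringsAsFactors = FALSE)
  }))
  validate_marginals(marg)
  labels <- marg$name
  target <- raw$target
  if (!target %in% labels) {
    stop("calibration target '", target, "' is not among the marginals")
  }
  factors <- setdiff(labels, target)
  m <- length(factors)

  block <- diag(m)
  dimnames(block) <- list(factors, factors)
  for (entry in raw$factor_correlations) {
    a <- entry$pair[[1]]; b <- entry$pair[[2]]
    if (!all(c(a, b) %in% factors)) {
      stop("correlation pair (", a, ", ", b, ") names an unknown factor")
    }
    block[a, b] <- block[b, a] <- entry$rho
  }
  tcol <- unlist(raw$target_correlations)[factors]
  if (anyNA(tcol)) stop("target_correlations must cover every factor")

  # the key is spelled sample_size: a bare `n:` is implicitly typed as a
  # YAML 1.1 boolean and would vanish from the parsed list
  n <- raw$sample_size
  if (is.null(n) || !is.numeric(n) || n < 2) {
    stop("calibration must give an integer sample_size >= 2")
  }
  corr <- build_correlation_matrix(block, tcol, target = target)
  structure(list(marginals = marg, correlation = corr,
                 target = target, n = as.integer(n)),
            class = "survey_calibration")
}

#' @rdname read_calibration
#' @export
default_calibration_path <- function() {
  system.file("extdata", "uk_survey_calibration.yaml", package = "safetybbn",
              mustWork = TRUE)
}

validate_marginals <- function(marg) {
  stopifnot(is.data.frame(marg),
            all(c("name", "mean", "sd", "low", "high", "scale_max") %in%
                  names(marg)))
  if (anyDuplicated(marg$name)) stop("duplicate variable names in marginals")
  bad <- with(marg, low >= high | low < 0 | high > scale_max | sd <= 0 |
                mean < low | mean > high)
  if (any(bad)) {
    stop("invalid marginal summary for: ",
         paste(marg$name[bad], collapse = ", "))
  }
  invisible(marg)
}

#' @export
print.survey_calibration <- function(x, ...) {
  cat("Survey calibration: ", nrow(x$marginals), " variables, target '",
      x$target, "', n = ", x$n, "\n", sep = "")
  print(x$marginals, row.names = FALSE)
  invisible(x)
}
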