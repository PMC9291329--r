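#' Fit a uniform-width discretization scheme
#'
#' Splits each variable's observed range into `k` equal-width intervals,
#' giving states s1..sk. Edges are fitted from the data's per-variable
#' min/max, not the theoretical scale bounds: at the calibrated dispersion
#' (SD far below scale range) binning on \[0, 10\] would leave most states
#' empty.
#'
#' @param table A `survey_table` (or any all-numeric data frame).
#' @param k Number of states per variable, 2 or 3.
#' @return A `discretization_scheme`: per-variable interior cutpoints (k-1
#'   values) plus the observed low/high used to fit.
#' @export
fit_uniform_width <- function(table, k) {
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3")
  k <- as.integer(k)
  labels <- names(table)
  lows <- vapply(table, min, numeric(1))
  highs <- vapply(table, max, numeric(1))
  const <- labels[highs <= lows]
  if (length(const)) {
    stop("constant column cannot be discretized: ",
         paste(const, collapse = ", "))
  }
  cuts <- lapply(labels, function(j) {
    lows[[j]] + (highs[[j]] - lows[[j]]) * seq_len(k - 1) / k
  })
  names(cuts) <- labels
  structure(list(labels = labels, k = k, cutpoints = cuts,
                 low = lows, high = highs),
            class = "discretization_scheme")
}

#' Apply a discretization scheme
#'
#' Maps each value to its state index in 1..k. Bins are left-closed /
#' right-open, except the last bin which is closed on both sides, so a value
#' exactly on an interior cutpoint takes the higher state and the observed
#' maximum takes state k. Values outside the fitted \[low, high\] (possible
#' when a scheme is reused on new data) clamp to the nearest extreme state;
#' the number of clamped cells is returned in the `clamped` attribute and
#' raised as a warning.
#'
#' @param scheme A `discretization_scheme`.
#' @param table A data frame with the same columns the scheme was fitted on.
#' @return A `discrete_data` object: integer matrix of state indices with
#'   attribute `k` (named per-variable cardinality) and `clamped`.
#' @export
apply_scheme <- function(scheme, table) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  if (!identical(sort(scheme$labels), sort(names(table)))) {
    stop("table columns do not match the scheme's variables")
  }
  n <- nrow(table)
  k <- scheme$k
  clamped <- 0L
  x <- vapply(scheme$labels, function(j) {
    v <- table[[j]]
    clamped <<- clamped + sum(v < scheme$low[[j]] | v > scheme$high[[j]])
    s <- findInterval(v, scheme$cutpoints[[j]]) + 1L
    pmin(pmax(s, 1L), k)
  }, integer(n))
  if (clamped > 0) {
    warning(clamped, " value(s) outside the fitted range were clamped ",
            "to an extreme state")
  }
  out <- new_discrete_data(x, rep_len(k, length(scheme$labels)))
  attr(out, "clamped") <- as.integer(clamped)
  out
}

#' Construct a discrete dataset from a state-index matrix
#'
#' Low-level constructor used by [apply_scheme()] and by tests that build
#' discrete fixtures directly.
#'
#' @param x Integer matrix of state indices (columns named).
#' @param k Per-variable state counts, recycled if scalar.
#' @return A `discrete_data` object.
#' @export
new_discrete_data <- function(x, k) {
  storage.mode(x) <- "integer"
  stopifnot(!is.null(colnames(x)))
  k <- stats::setNames(rep_len(as.integer(k), ncol(x)), colnames(x))
  if (any(x < 1L) || any(x > k[col(x)])) stop("state index out of range")
  structure(x, k = k, class = "discrete_data")
}

#' @export
print.discrete_data <- function(x, ...) {
  cat("Discrete dataset:", nrow(x), "records,", ncol(x), "variables, states",
      paste0("s1..s", max(attr(x, "k"))), "\n")
  invisible(x)
}

#' State cardinalities of a discrete dataset
#' @param data A `discrete_data` object.
#' @return Named integer vector of per-variable state counts.
#' @export
cardinalities <- function(data) attr(data, "k")

#' Serialize a discretization scheme to / from JSON
#'
#' @param scheme A `discretization_scheme`.
#' @param path File path.
#' @return `scheme_from_json()` returns the scheme; `scheme_to_json()`
#'   returns `path` invisibly.
#' @export
scheme_to_json <- function(scheme, path) {
  payload <- list(labels = scheme$labels, k = scheme$k,
                  cutpoints = scheme$cutpoints,
                  low = as.list(scheme$low), high = as.list(scheme$high))
  # digits = I(17) round-trips doubles exactly; the default significant-digit
  # mode can shift a cutpoint by ~1e-16 and change a boundary assignment
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname scheme_to_json
#' @export
scheme_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(labels = raw$labels, k = as.integer(raw$k),
                 cutpoints = as.list(raw$cutpoints),
                 low = unlist(raw$low), high = unlist(raw$high)),
            class = "discretization_scheme")
}
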