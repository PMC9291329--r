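#' G-squared conditional independence test
#'
#' Likelihood-ratio test of X independent of Y given a (possibly empty) set
#' of conditioning variables, on discretized survey data. Within each
#' conditioning stratum the statistic is 2 * sum O * ln(O / E) over the
#' X x Y contingency table, with E from the stratum's row/column margins
#' and 0 * ln 0 = 0. Degrees of freedom are (kx - 1)(ky - 1) per non-empty
#' stratum, reduced to (non-empty rows - 1)(non-empty columns - 1) in
#' degenerate strata where whole rows or columns are unobserved — standard
#' practice for sparse three-state tables at a few hundred records. The
#' p-value is the chi-square upper tail.
#'
#' @param data A `discrete_data` object.
#' @param x,y Variable labels, distinct, not in `cond`.
#' @param cond Character vector of conditioning variable labels.
#' @return A list of class `ci_test_result`: `statistic`, `dof`, `p_value`,
#'   `x`, `y`, `cond_set`.
#' @export
g2_ci_test <- function(data, x, y, cond = character(0)) {
  if (x == y) stop("x and y must differ")
  if (x %in% cond || y %in% cond) stop("x and y must not appear in cond")
  k <- cardinalities(data)
  kx <- k[[x]]
  ky <- k[[y]]
  xi <- data[, x]
  yi <- data[, y]
  if (length(cond)) {
    # stratum index from mixed-radix encoding of the conditioning states
    s <- rep(0L, nrow(data))
    for (v in cond) s <- s * k[[v]] + (data[, v] - 1L)
    strata <- s
  } else {
    strata <- rep(0L, nrow(data))
  }
  g2 <- 0
  dof <- 0L
  for (s in unique(strata)) {
    sel <- strata == s
    tab <- table(factor(xi[sel], levels = seq_len(kx)),
                 factor(yi[sel], levels = seq_len(ky)))
    nt <- sum(tab)
    if (nt == 0) next
    rs <- rowSums(tab)
    cs <- colSums(tab)
    expd <- outer(rs, cs) / nt
    nz <- tab > 0
    g2 <- g2 + 2 * sum(tab[nz] * log(tab[nz] / expd[nz]))
    dof <- dof + max(sum(rs > 0) - 1L, 0L) * max(sum(cs > 0) - 1L, 0L)
  }
  dof <- max(dof, 1L)
  structure(list(statistic = g2, dof = dof,
                 p_value = stats::pchisq(g2, dof, lower.tail = FALSE),
                 x = x, y = y, cond_set = cond),
            class = "ci_test_result")
}

#' @export
print.ci_test_result <- function(x, ...) {
  cond <- if (length(x$cond_set)) paste(x$cond_set, collapse = ", ") else "{}"
  cat(sprintf("G2(%s, %s | %s) = %.4f, df = %d, p = %.4g\n",
              x$x, x$y, cond, x$statistic, x$dof, x$p_value))
  invisible(x)
}
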