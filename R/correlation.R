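#' Assemble the full Spearman correlation matrix
#'
#' Joins the inter-factor correlation block with the factor-target column
#' into one symmetric matrix over all variables, and repairs it to the
#' nearest positive-definite matrix if the assembly is indefinite (printed
#' correlation tables, rounded to two decimals, carry no PD guarantee).
#'
#' @param factor_block Symmetric m x m matrix of inter-factor Spearman
#'   coefficients with unit diagonal; must carry dimnames.
#' @param target_column Named length-m vector of factor-target Spearman
#'   coefficients, in the same order as `factor_block`.
#' @param target Name for the target variable (last row/column).
#' @return An (m+1) x (m+1) correlation matrix with attributes
#'   `repaired` (logical) and `max_perturbation` (largest absolute change
#'   any entry underwent during repair; 0 when no repair was needed).
#' @export
build_correlation_matrix <- function(factor_block, target_column,
                                     target = "patient_safety_errors") {
  m <- nrow(factor_block)
  if (is.null(rownames(factor_block))) {
    stop("factor_block must have row/column names")
  }
  if (!isTRUE(all.equal(factor_block, t(factor_block), tolerance = 1e-12))) {
    stop("factor_block must be symmetric")
  }
  if (any(abs(diag(factor_block) - 1) > 1e-12)) {
    stop("factor_block must have a unit diagonal")
  }
  if (any(abs(factor_block) > 1) || any(abs(target_column) > 1)) {
    stop("correlation entries must lie in [-1, 1]")
  }
  if (length(target_column) != m) {
    stop("target_column length must match factor_block dimension")
  }
  labels <- c(rownames(factor_block), target)
  full <- diag(m + 1)
  full[seq_len(m), seq_len(m)] <- factor_block
  full[m + 1, seq_len(m)] <- target_column
  full[seq_len(m), m + 1] <- target_column
  dimnames(full) <- list(labels, labels)
  repair_correlation(full)
}

#' Repair an indefinite correlation matrix
#'
#' Eigenvalue clipping at `eps` followed by rescaling the diagonal back to 1,
#' iterated until the smallest eigenvalue reaches `eps` (rescaling is a
#' congruence transform so positivity is preserved, but the floor can shift
#' slightly). A matrix that is already positive definite is returned as is.
#'
#' @param rho Symmetric correlation matrix.
#' @param eps Eigenvalue floor.
#' @return The repaired matrix with attributes `repaired` and
#'   `max_perturbation`.
#' @export
repair_correlation <- function(rho, eps = 1e-8) {
  orig <- rho
  repaired <- FALSE
  for (i in 1:100) {
    ev <- eigen(rho, symmetric = TRUE)
    if (min(ev$values) >= eps) break
    repaired <- TRUE
    lam <- pmax(ev$values, eps)
    rho <- ev$vectors %*% (lam * t(ev$vectors))
    d <- 1 / sqrt(diag(rho))
    rho <- rho * tcrossprod(d)
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
  }
  lam_min <- min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min < eps) {
    # the alternating projection can stall on the PSD boundary; a convex
    # blend with the identity lifts the spectrum while keeping unit diagonal
    delta <- (eps - lam_min) / (1 - eps) + 1e-12
    rho <- (rho + delta * diag(nrow(rho))) / (1 + delta)
  }
  if (min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values) < eps) {
    stop("correlation repair failed to reach the eigenvalue floor")
  }
  dimnames(rho) <- dimnames(orig)
  structure(rho, repaired = repaired,
            max_perturbation = max(abs(rho - orig)))
}

#' Spearman to latent Pearson correlation
#'
#' For a Gaussian copula, a latent Pearson correlation r induces Spearman
#' rank correlation (6/pi) asin(r/2) between the margins; the inverse map
#' 2 sin(pi rho / 6) calibrates the latent normal so the generated sample
#' attains a prescribed Spearman coefficient.
#'
#' @param rho_s Spearman coefficient(s) in \[-1, 1\] (vector or matrix).
#' @return Latent Pearson correlation(s), same shape as the input.
#' @export
#' @examples
#' spearman_to_latent_pearson(0.5) # 2*sin(pi/12) = 0.5176381
spearman_to_latent_pearson <- function(rho_s) {
  if (any(abs(rho_s) > 1)) stop("Spearman coefficients must lie in [-1, 1]")
  2 * sin(pi * rho_s / 6)
}
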