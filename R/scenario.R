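#' Backward propagation of beliefs from the target
#'
#' Conditions the network on a state of the outcome node and reports how
#' every factor's posterior moves away from its prior, summarized by total
#' variation distance (half the L1 difference), sorted by decreasing
#' change.
#'
#' @param net A `bayes_net`.
#' @param target Outcome node label.
#' @param target_state State of the outcome to condition on.
#' @return A list with `posteriors` (per-factor distributions), `priors`,
#'   and `change` (named, sorted decreasing total-variation change).
#' @export
backward_propagation <- function(net, target, target_state) {
  ev <- stats::setNames(as.integer(target_state), target)
  priors <- posterior_marginals(net)
  posts <- posterior_marginals(net, ev)
  factors <- setdiff(net$dag$nodes, target)
  change <- vapply(factors, function(f) {
    sum(abs(posts[[f]] - priors[[f]])) / 2
  }, numeric(1))
  list(posteriors = posts[factors], priors = priors[factors],
       change = sort(change, decreasing = TRUE))
}

#' Vulnerability / resilience impact assessment
#'
#' For every factor, measures the change in the probability of the worst
#' outcome state when the factor is observed in its own worst (s1) and best
#' (s_k) states, relative to the prior baseline. Factor scores are coded so
#' that s1 is the least favorable band; the worst outcome state is the
#' highest error band (s_k of the target). Deltas are percentage points of
#' P(target = worst state): `delta_s1` is the vulnerability reading,
#' `delta_s3` the resilience reading. A factor state of zero prior
#' probability yields an NA delta with a warning.
#'
#' @param net A `bayes_net`.
#' @param target Outcome node label.
#' @param worst_target_state Outcome state regarded as worst; defaults to
#'   the target's highest state.
#' @return An `impact_assessment` data frame (factor, delta_s1, delta_s3)
#'   with attribute `baseline` (prior P(target = worst), as a probability).
#' @export
impact_assessment <- function(net, target,
                              worst_target_state = net$k[[target]]) {
  factors <- setdiff(net$dag$nodes, target)
  priors <- posterior_marginals(net)
  baseline <- priors[[target]][worst_target_state]
  delta <- function(f, state) {
    if (priors[[f]][state] <= 0) {
      warning("factor '", f, "' state ", state,
              " has zero prior probability; delta undefined")
      return(NA_real_)
    }
    ev <- stats::setNames(as.integer(state), f)
    post <- posterior_distribution(net, target, ev)
    100 * (post[worst_target_state] - baseline)
  }
  out <- data.frame(
    factor = factors,
    delta_s1 = vapply(factors, function(f) delta(f, 1L), numeric(1)),
    delta_s3 = vapply(factors, function(f) delta(f, net$k[[f]]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, baseline = as.numeric(baseline),
            class = c("impact_assessment", "data.frame"))
}

#' Rank factors by vulnerability or resilience
#'
#' Vulnerability ranks order factors by decreasing `delta_s1` (the largest
#' increase in the worst-outcome probability gets rank 1); resilience ranks
#' order by increasing `delta_s3` (the largest reduction gets rank 1, and
#' factors whose best state raises the probability sort last). Exact ties
#' receive the average of the positions they straddle, so rank sums stay at
#' m(m+1)/2.
#'
#' @param impact An `impact_assessment`.
#' @param mode "vulnerability" or "resilience".
#' @return A `ranking_scheme` data frame (factor, rank) with attribute
#'   `mode`. Factors with undefined deltas are excluded with a warning.
#' @export
rank_factors <- function(impact, mode = c("vulnerability", "resilience")) {
  mode <- match.arg(mode)
  val <- if (mode == "vulnerability") impact$delta_s1 else impact$delta_s3
  keep <- !is.na(val)
  if (!all(keep)) {
    warning("excluding factors with undefined deltas: ",
            paste(impact$factor[!keep], collapse = ", "))
  }
  val <- val[keep]
  rk <- if (mode == "vulnerability") rank(-val, ties.method = "average")
        else rank(val, ties.method = "average")
  structure(data.frame(factor = impact$factor[keep], rank = rk,
                       stringsAsFactors = FALSE, row.names = NULL),
            mode = mode, class = c("ranking_scheme", "data.frame"))
}

#' Tie-corrected Spearman correlation of two ranking schemes
#'
#' With average ranks already assigned, the tie-corrected Spearman
#' coefficient is the Pearson correlation of the two rank vectors (which
#' reduces to 1 - 6 sum d^2 / (m^3 - m) when no ties are present).
#'
#' @param a,b `ranking_scheme` objects (or data frames with `factor` and
#'   `rank` columns) over the same factors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
spearman_rank_corr <- function(a, b) {
  if (!setequal(a$factor, b$factor) || nrow(a) < 2) {
    stop("rankings must cover the same factors, with at least two")
  }
  bb <- b$rank[match(a$factor, b$factor)]
  if (stats::sd(a$rank) == 0 || stats::sd(bb) == 0) {
    stop("a ranking with zero variance has no defined rank correlation")
  }
  stats::cor(a$rank, bb)
}
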