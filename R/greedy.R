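#' Greedy thick thinning (GTT) structure learning
#'
#' Score-based learner in two phases under the BDeu score. Thickening:
#' starting from the empty graph, repeatedly add the acyclicity-preserving
#' arc with the largest positive score gain until none improves. Thinning:
#' repeatedly delete the arc whose removal most improves the score until no
#' deletion improves. Ties break lexicographically on (parent, child), so
#' the result is deterministic.
#'
#' @param data A `discrete_data` object.
#' @param ess Equivalent sample size of the BDeu prior (default 1).
#' @return A `dag`. The accepted-move score trajectory is attached as
#'   attribute `score_trace`; the final score as attribute `score`.
#' @export
learn_gtt <- function(data, ess = 1) {
  labels <- colnames(data)
  g <- new_dag(labels)
  cache <- new.env(parent = emptyenv())
  fam <- function(v, pa) bdeu_family_score(data, v, pa, ess, cache)
  trace <- bdeu_score_cached(g, fam)

  # thickening
  repeat {
    best <- best_arc_change(g, fam, mode = "add")
    if (is.null(best)) break
    g <- add_edge(g, best$from, best$to)
    trace <- c(trace, trace[length(trace)] + best$gain)
  }
  # thinning
  repeat {
    best <- best_arc_change(g, fam, mode = "delete")
    if (is.null(best)) break
    g <- remove_edge(g, best$from, best$to)
    trace <- c(trace, trace[length(trace)] + best$gain)
  }
  structure(g, score = trace[length(trace)], score_trace = trace)
}

bdeu_score_cached <- function(g, fam) {
  sum(vapply(g$nodes, function(v) fam(v, parents(g, v)), numeric(1)))
}

# Best single-arc addition or deletion by score gain; NULL when no change
# has positive gain. Deterministic lexicographic tie-break.
best_arc_change <- function(g, fam, mode) {
  labels <- g$nodes
  best <- NULL
  for (from in sort(labels)) {
    for (to in sort(labels)) {
      if (from == to) next
      if (mode == "add") {
        if (g$amat[from, to] == 1L || g$amat[to, from] == 1L) next
        if (!addition_is_acyclic(g, from, to)) next
        pa_new <- sort(c(parents(g, to), from))
      } else {
        if (g$amat[from, to] != 1L) next
        pa_new <- setdiff(parents(g, to), from)
      }
      gain <- fam(to, pa_new) - fam(to, parents(g, to))
      if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12)) {
        best <- list(from = from, to = to, gain = gain)
      }
    }
  }
  best
}

#' Bayesian search structure learning
#'
#' Hill climbing over single-arc moves (add, delete, reverse) maximizing
#' the BDeu score, with random restarts. The first climb starts from the
#' empty graph; each further restart starts from a random DAG. The
#' highest-scoring structure across restarts is returned. Deterministic
#' given the seed.
#'
#' @param data A `discrete_data` object.
#' @param restarts Number of climbs (>= 1); default 20.
#' @param max_iter Maximum accepted moves per climb; default 500.
#' @param ess BDeu equivalent sample size; default 1.
#' @param seed Integer seed for the restart graphs.
#' @return A `dag` with attributes `score` and `score_trace` (trajectory of
#'   the winning climb).
#' @export
learn_bayesian_search <- function(data, restarts = 20, max_iter = 500,
                                  ess = 1, seed = 1) {
  if (restarts < 1) stop("restarts must be >= 1")
  labels <- colnames(data)
  cache <- new.env(parent = emptyenv())
  fam <- function(v, pa) bdeu_family_score(data, v, pa, ess, cache)

  starts <- withr::with_seed(seed, {
    c(list(new_dag(labels)),
      lapply(seq_len(restarts - 1), function(i) random_dag(labels, 0.25)))
  })
  best <- NULL
  for (g0 in starts) {
    res <- hill_climb(g0, fam, max_iter)
    if (is.null(best) || attr(res, "score") > attr(best, "score")) best <- res
  }
  best
}

hill_climb <- function(g, fam, max_iter) {
  trace <- bdeu_score_cached(g, fam)
  for (i in seq_len(max_iter)) {
    best <- NULL
    for (mode in c("add", "delete")) {
      cand <- best_arc_change(g, fam, mode)
      if (!is.null(cand) && (is.null(best) || cand$gain > best$gain + 1e-12)) {
        best <- c(cand, mode = mode)
      }
    }
    rev <- best_reversal(g, fam)
    if (!is.null(rev) && (is.null(best) || rev$gain > best$gain + 1e-12)) {
      best <- c(rev, mode = "reverse")
    }
    if (is.null(best)) break
    g <- switch(best$mode,
      add = add_edge(g, best$from, best$to),
      delete = remove_edge(g, best$from, best$to),
      reverse = add_edge(remove_edge(g, best$from, best$to),
                         best$to, best$from))
    trace <- c(trace, trace[length(trace)] + best$gain)
  }
  structure(g, score = trace[length(trace)], score_trace = trace)
}

best_reversal <- function(g, fam) {
  e <- edge_list(g)
  best <- NULL
  for (r in seq_len(NROW(e))) {
    from <- e[r, 1]; to <- e[r, 2]
    g2 <- remove_edge(g, from, to)
    if (!addition_is_acyclic(g2, to, from)) next
    gain <- (fam(to, setdiff(parents(g, to), from)) -
               fam(to, parents(g, to))) +
      (fam(from, sort(c(parents(g, from), to))) - fam(from, parents(g, from)))
    if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12)) {
      best <- list(from = from, to = to, gain = gain)
    }
  }
  best
}

#' Draw a random DAG
#'
#' Orients each possible edge of an Erdos-Renyi graph along a random
#' permutation of the nodes, guaranteeing acyclicity. Used for hill-climbing
#' restarts and for randomized test nets.
#'
#' @param labels Node labels.
#' @param p_edge Probability each ordered-by-permutation pair gets an arc.
#' @return A `dag`.
#' @export
random_dag <- function(labels, p_edge = 0.25) {
  ord <- sample(labels)
  edges <- NULL
  m <- length(labels)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (stats::runif(1) < p_edge) edges <- rbind(edges, c(ord[i], ord[j]))
    }
  }
  new_dag(labels, edges)
}
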