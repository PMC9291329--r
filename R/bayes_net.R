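#' Fit conditional probability tables on a DAG
#'
#' Parameterizes each node with a CPT row per parent-state combination,
#' using Dirichlet-smoothed relative frequencies
#' (count + alpha) / (row total + k * alpha). With up to three 3-state
#' parents at a few hundred records some parent combinations are never
#' observed, so the default alpha = 1 keeps every row a proper
#' distribution; alpha = 0 gives maximum-likelihood rows and fails loudly
#' on unobserved combinations.
#'
#' @param dag A `dag` over the data's variables.
#' @param data A `discrete_data` object.
#' @param alpha Pseudocount added to every cell (>= 0), default 1.
#' @return A `bayes_net`: list with `dag`, `cpts` (per node: `parents` and
#'   a q x k row-stochastic `prob` matrix, rows indexed by the mixed-radix
#'   parent configuration with the first parent most significant) and `k`.
#' @export
fit_cpts <- function(dag, data, alpha = 1) {
  stopifnot(setequal(dag$nodes, colnames(data)))
  if (alpha < 0) stop("alpha must be >= 0")
  k <- cardinalities(data)
  cpts <- lapply(dag$nodes, function(v) {
    pa <- parents(dag, v)
    r <- k[[v]]
    q <- if (length(pa)) prod(k[pa]) else 1L
    cfg <- rep(1L, nrow(data))
    for (u in pa) cfg <- (cfg - 1L) * k[[u]] + data[, u]
    counts <- unclass(table(factor(cfg, levels = seq_len(q)),
                            factor(data[, v], levels = seq_len(r))))
    tot <- rowSums(counts)
    if (alpha == 0 && any(tot == 0)) {
      stop("node '", v, "': parent configuration ", which(tot == 0)[1],
           " unobserved; alpha = 0 cannot normalize the row")
    }
    prob <- (counts + alpha) / (tot + r * alpha)
    dimnames(prob) <- NULL
    list(parents = pa, prob = prob)
  })
  names(cpts) <- dag$nodes
  structure(list(dag = dag, cpts = cpts, k = k), class = "bayes_net")
}

#' @export
print.bayes_net <- function(x, ...) {
  cat("Bayesian network:", length(x$dag$nodes), "nodes,", n_edges(x$dag),
      "arcs, cardinalities", paste(unique(x$k), collapse = "/"), "\n")
  invisible(x)
}

cpt_row_index <- function(net, v, assignment) {
  pa <- net$cpts[[v]]$parents
  cfg <- 1L
  for (u in pa) cfg <- (cfg - 1L) * net$k[[u]] + assignment[[u]]
  cfg
}

#' Joint probability of a full assignment
#'
#' The chain-rule product prod_i P(Xi = xi | pa(Xi)) over every node of the
#' network.
#'
#' @param net A `bayes_net`.
#' @param assignment Named integer vector giving one state per node.
#' @return A single probability.
#' @export
joint_probability <- function(net, assignment) {
  nodes <- net$dag$nodes
  if (!all(nodes %in% names(assignment))) {
    stop("assignment must cover every node of the network")
  }
  prod(vapply(nodes, function(v) {
    net$cpts[[v]]$prob[cpt_row_index(net, v, assignment), assignment[[v]]]
  }, numeric(1)))
}

# ---- discrete factors -------------------------------------------------

# A factor is list(vars, tab): tab an array with dim = k[vars], linear
# order column-major (first var fastest), matching expand.grid.
cpt_factor <- function(net, v) {
  pa <- net$cpts[[v]]$parents
  vars <- c(pa, v)
  dims <- as.integer(net$k[vars])
  grid <- as.matrix(expand.grid(lapply(dims, seq_len)))
  colnames(grid) <- vars
  row <- rep(1L, nrow(grid))
  for (u in pa) row <- (row - 1L) * net$k[[u]] + grid[, u]
  tab <- array(net$cpts[[v]]$prob[cbind(row, grid[, v])], dim = dims)
  list(vars = vars, tab = tab)
}

factor_reduce <- function(f, evidence) {
  keep <- setdiff(f$vars, names(evidence))
  if (length(keep) == length(f$vars)) return(f)
  idx <- lapply(f$vars, function(v) {
    if (v %in% names(evidence)) evidence[[v]] else TRUE
  })
  tab <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
  dims <- dim(tab)[f$vars %in% keep]
  list(vars = keep, tab = array(tab, dim = if (length(keep)) dims else 1))
}

factor_product <- function(f1, f2, k) {
  vars <- union(f1$vars, f2$vars)
  if (!length(vars)) {
    return(list(vars = character(0),
                tab = array(as.numeric(f1$tab) * as.numeric(f2$tab), 1)))
  }
  dims <- as.integer(k[vars])
  grid <- as.matrix(expand.grid(lapply(dims, seq_len)))
  colnames(grid) <- vars
  val1 <- if (length(f1$vars)) {
    f1$tab[grid[, f1$vars, drop = FALSE]]
  } else {
    as.numeric(f1$tab)
  }
  val2 <- if (length(f2$vars)) {
    f2$tab[grid[, f2$vars, drop = FALSE]]
  } else {
    as.numeric(f2$tab)
  }
  list(vars = vars, tab = array(val1 * val2, dim = dims))
}

factor_marginalize <- function(f, var) {
  keep <- which(f$vars != var)
  if (!length(keep)) {
    return(list(vars = character(0), tab = array(sum(f$tab), 1)))
  }
  tab <- apply(f$tab, keep, sum)
  list(vars = f$vars[keep], tab = array(tab, dim = dim(f$tab)[keep]))
}

# Eliminate `elim` variables from a factor list by min-degree order.
eliminate <- function(factors, elim, k) {
  while (length(elim)) {
    # min-degree: variable appearing with the fewest distinct neighbors
    degree <- vapply(elim, function(v) {
      nb <- unique(unlist(lapply(factors, function(f) {
        if (v %in% f$vars) f$vars else NULL
      })))
      length(setdiff(nb, v))
    }, numeric(1))
    v <- elim[order(degree, elim)][1]
    elim <- setdiff(elim, v)
    inv <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod <- Reduce(function(a, b) factor_product(a, b, k), factors[inv])
    factors <- c(factors[!inv], list(factor_marginalize(prod, v)))
  }
  factors
}

#' Exact posterior marginals by variable elimination
#'
#' Conditions the network on an evidence scenario (a named vector of
#' observed states) and returns the exact posterior distribution of every
#' node, computed by variable elimination with a min-degree ordering. At
#' nine nodes any ordering is tractable; the implementation is validated
#' against full-joint enumeration in the test suite.
#'
#' @param net A `bayes_net`.
#' @param evidence Named integer vector of observed states (may be empty).
#' @return A named list of probability vectors, one per node (evidence
#'   nodes get a point mass), with attribute `p_evidence`.
#' @export
posterior_marginals <- function(net, evidence = integer(0)) {
  check_evidence(net, evidence)
  nodes <- net$dag$nodes
  base <- lapply(nodes, function(v) factor_reduce(cpt_factor(net, v), evidence))
  pe <- NULL
  out <- vector("list", length(nodes))
  names(out) <- nodes
  for (q in nodes) {
    elim <- setdiff(nodes, c(q, names(evidence)))
    fs <- eliminate(base, elim, net$k)
    f <- Reduce(function(a, b) factor_product(a, b, net$k), fs)
    if (q %in% names(evidence)) {
      z <- sum(f$tab)
      dist <- rep(0, net$k[[q]])
      dist[evidence[[q]]] <- 1
    } else {
      z <- sum(f$tab)
      dist <- as.numeric(f$tab) / z
    }
    if (is.null(pe)) {
      pe <- z
      if (pe <= 0) stop("evidence scenario has zero probability")
    }
    out[[q]] <- dist
  }
  attr(out, "p_evidence") <- pe
  out
}

check_evidence <- function(net, evidence) {
  if (!length(evidence)) return(invisible())
  if (is.null(names(evidence)) || !all(names(evidence) %in% net$dag$nodes)) {
    stop("evidence names must be nodes of the network")
  }
  bad <- names(evidence)[evidence < 1 | evidence > net$k[names(evidence)]]
  if (length(bad)) stop("evidence state out of range for: ",
                        paste(bad, collapse = ", "))
  invisible()
}

#' Posterior distribution of a single node
#'
#' @param net A `bayes_net`.
#' @param node Query node label.
#' @param evidence Named integer vector of observed states.
#' @return Probability vector over the node's states.
#' @export
posterior_distribution <- function(net, node, evidence = integer(0)) {
  check_evidence(net, evidence)
  if (node %in% names(evidence)) {
    dist <- rep(0, net$k[[node]])
    dist[evidence[[node]]] <- 1
    return(dist)
  }
  base <- lapply(net$dag$nodes,
                 function(v) factor_reduce(cpt_factor(net, v), evidence))
  elim <- setdiff(net$dag$nodes, c(node, names(evidence)))
  fs <- eliminate(base, elim, net$k)
  f <- Reduce(function(a, b) factor_product(a, b, net$k), fs)
  z <- sum(f$tab)
  if (z <= 0) stop("evidence scenario has zero probability")
  as.numeric(f$tab) / z
}

#' Maximum-a-posteriori prediction of a target node
#'
#' Uses every non-target assignment of a record as evidence and returns the
#' argmax state of the target's posterior; ties break toward the lowest
#' state index. A zero-probability evidence configuration falls back to the
#' target's prior MAP (counted in the `fallbacks` attribute).
#'
#' @param net A `bayes_net`.
#' @param record Named integer vector of states for all non-target nodes.
#' @param target Target node label.
#' @return Predicted state index.
#' @export
predict_map <- function(net, record, target) {
  needed <- setdiff(net$dag$nodes, target)
  if (!all(needed %in% names(record))) {
    stop("record must cover every node except the target")
  }
  record <- record[needed]
  post <- tryCatch(posterior_distribution(net, target, record),
                   error = function(e) NULL)
  fallback <- 0L
  if (is.null(post)) {
    post <- posterior_distribution(net, target)
    fallback <- 1L
  }
  structure(which.max(post), fallbacks = fallback)
}

#' Serialize a Bayesian network to / from JSON
#'
#' Structure plus CPT rows, written exactly (no digit rounding), so the
#' round trip is lossless to machine precision.
#'
#' @param net A `bayes_net`.
#' @param path File path.
#' @return `net_from_json()` returns the `bayes_net`; `net_to_json()`
#'   returns `path` invisibly.
#' @export
net_to_json <- function(net, path) {
  payload <- list(
    nodes = net$dag$nodes,
    edges = edge_list(net$dag),
    k = as.list(net$k),
    cpts = lapply(net$cpts, function(cpt) {
      list(parents = cpt$parents, prob = cpt$prob)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname net_to_json
#' @export
net_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(raw$edges)) as.matrix(raw$edges) else NULL
  dag <- new_dag(raw$nodes, edges)
  k <- unlist(raw$k)[raw$nodes]
  cpts <- lapply(raw$nodes, function(v) {
    cpt <- raw$cpts[[v]]
    prob <- cpt$prob
    if (!is.matrix(prob)) prob <- matrix(prob, nrow = 1)
    list(parents = as.character(unlist(cpt$parents %||% character(0))),
         prob = prob)
  })
  names(cpts) <- raw$nodes
  structure(list(dag = dag, cpts = cpts,
                 k = stats::setNames(as.integer(k), raw$nodes)),
            class = "bayes_net")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
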