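# Shared fixtures: hand-built nets, random nets with Dirichlet CPTs, and a
# brute-force full-joint enumeration oracle kept independent of the
# variable-elimination engine.

oracle_indep <- function(g) function(x, y, cond) d_separated(g, x, y, cond)

# placeholder dataset: gives learners a label/cardinality frame when the
# independence oracle replaces the data-driven test
dummy_discrete <- function(labels, k = 2L, n = 10L) {
  new_discrete_data(matrix(1L, n, length(labels),
                           dimnames = list(NULL, labels)), k)
}

# random network: random DAG + Dirichlet(1) CPT rows
random_net <- function(labels, k = 3L, p_edge = 0.3) {
  dag <- random_dag(labels, p_edge)
  kk <- stats::setNames(rep_len(as.integer(k), length(labels)), labels)
  cpts <- lapply(labels, function(v) {
    pa <- parents(dag, v)
    q <- if (length(pa)) prod(kk[pa]) else 1L
    prob <- matrix(stats::rgamma(q * kk[[v]], 1), q, kk[[v]])
    prob <- prob / rowSums(prob)
    list(parents = pa, prob = prob)
  })
  names(cpts) <- labels
  structure(list(dag = dag, cpts = cpts, k = kk), class = "bayes_net")
}

# manual net constructor: cpts = named list(list(parents=, prob=))
manual_net <- function(nodes, edges, cpts, k) {
  dag <- new_dag(nodes, edges)
  kk <- stats::setNames(rep_len(as.integer(k), length(nodes)), nodes)
  structure(list(dag = dag, cpts = cpts[nodes], k = kk), class = "bayes_net")
}

# full-joint table by direct chain-rule evaluation over every assignment
enum_joint <- function(net) {
  nodes <- net$dag$nodes
  grid <- as.matrix(expand.grid(lapply(net$k[nodes], seq_len)))
  colnames(grid) <- nodes
  p <- rep(1, nrow(grid))
  for (v in nodes) {
    pa <- net$cpts[[v]]$parents
    row <- rep(1L, nrow(grid))
    for (u in pa) row <- (row - 1L) * net$k[[u]] + grid[, u]
    p <- p * net$cpts[[v]]$prob[cbind(row, grid[, v])]
  }
  list(grid = grid, p = p)
}

# enumeration oracle for posterior marginals under evidence
enum_marginals <- function(net, evidence = integer(0)) {
  ej <- enum_joint(net)
  keep <- rep(TRUE, nrow(ej$grid))
  for (v in names(evidence)) keep <- keep & ej$grid[, v] == evidence[[v]]
  pz <- sum(ej$p[keep])
  out <- lapply(net$dag$nodes, function(v) {
    vapply(seq_len(net$k[[v]]), function(s) {
      sum(ej$p[keep & ej$grid[, v] == s])
    }, numeric(1)) / pz
  })
  names(out) <- net$dag$nodes
  attr(out, "p_evidence") <- pz
  out
}

# synthetic 9-variable table at the packaged calibration
calibrated_survey <- function(n, seed) {
  cal <- read_calibration()
  generate_survey(cal$marginals, cal$correlation, n = n, seed = seed)
}

factor_labels <- function() {
  setdiff(read_calibration()$marginals$name, "patient_safety_errors")
}
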