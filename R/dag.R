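#' Directed acyclic graphs over survey variables
#'
#' A `dag` is a node label vector plus a binary adjacency matrix
#' (`amat[i, j] == 1L` means an arc i -> j). Constructors reject cycles,
#' self-loops and duplicate arcs.
#'
#' @param nodes Character vector of node labels.
#' @param edges Two-column character matrix (or data frame) of
#'   (parent, child) arcs; may be empty.
#' @return An object of class `dag`.
#' @export
#' @examples
#' g <- new_dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' parents(g, "c")
new_dag <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns (parent, child)")
    if (!all(edges %in% nodes)) stop("edge endpoint not among the nodes")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
      stop("duplicate arcs are not allowed")
    }
    amat[cbind(edges[, 1], edges[, 2])] <- 1L
  }
  g <- structure(list(nodes = nodes, amat = amat), class = "dag")
  if (!is_acyclic(g)) stop("the arc set contains a directed cycle")
  g
}

#' @param g A `dag`.
#' @rdname new_dag
#' @export
is_acyclic <- function(g) {
  length(topological_order(g$amat)) == length(g$nodes)
}

# Kahn's algorithm; returns a partial order (shorter than p when cyclic).
topological_order <- function(amat) {
  p <- nrow(amat)
  indeg <- colSums(amat)
  order <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    ch <- which(amat[v, ] == 1L)
    indeg[ch] <- indeg[ch] - 1L
    newly <- ch[!is.na(indeg[ch]) & indeg[ch] == 0]
    indeg[newly] <- NA
    avail <- c(avail, newly)
  }
  order
}

#' @param node A node label.
#' @rdname new_dag
#' @export
parents <- function(g, node) g$nodes[g$amat[, node] == 1L]

#' @rdname new_dag
#' @export
children <- function(g, node) g$nodes[g$amat[node, ] == 1L]

#' @rdname new_dag
#' @export
edge_list <- function(g) {
  idx <- which(g$amat == 1L, arr.ind = TRUE)
  out <- cbind(parent = g$nodes[idx[, 1]], child = g$nodes[idx[, 2]])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' @rdname new_dag
#' @export
n_edges <- function(g) sum(g$amat)

#' @export
print.dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes and", n_edges(x), "arcs\n")
  e <- edge_list(x)
  if (nrow(e)) {
    apply(e, 1, function(r) cat(" ", r[1], "->", r[2], "\n"))
  }
  invisible(x)
}

add_edge <- function(g, from, to) {
  g$amat[from, to] <- 1L
  g
}

remove_edge <- function(g, from, to) {
  g$amat[from, to] <- 0L
  g
}

# TRUE when adding from -> to keeps the graph acyclic: no directed path
# to ~> from may exist.
addition_is_acyclic <- function(g, from, to) {
  !has_directed_path(g$amat, to, from)
}

has_directed_path <- function(amat, from, to) {
  seen <- rep(FALSE, nrow(amat))
  frontier <- which(rownames(amat) == from)
  while (length(frontier)) {
    seen[frontier] <- TRUE
    frontier <- which(colSums(amat[frontier, , drop = FALSE]) > 0 & !seen)
  }
  seen[which(rownames(amat) == to)]
}

ancestors_of <- function(amat, nodes) {
  # nodes: integer indices; returns indices of nodes plus all ancestors
  seen <- rep(FALSE, nrow(amat))
  frontier <- nodes
  while (length(frontier)) {
    seen[frontier] <- TRUE
    frontier <- which(rowSums(amat[, frontier, drop = FALSE]) > 0 & !seen)
  }
  which(seen)
}

#' Test d-separation in a DAG
#'
#' Uses the moralized-ancestral-graph criterion: restrict to the ancestors
#' of x, y and z, marry co-parents, drop arc directions, delete z, and test
#' whether x and y are still connected. This is the graphical ground truth
#' for conditional independence in the network and serves as an exact
#' oracle when checking constraint-based learners.
#'
#' @param g A `dag`.
#' @param x,y Node labels.
#' @param z Character vector of conditioning node labels (may be empty).
#' @return TRUE if x and y are d-separated given z.
#' @export
d_separated <- function(g, x, y, z = character(0)) {
  stopifnot(x != y, !x %in% z, !y %in% z)
  amat <- g$amat
  idx <- match(c(x, y, z), g$nodes)
  keep <- ancestors_of(amat, idx)
  sub <- amat[keep, keep, drop = FALSE]
  # moralize: connect parents sharing a child, then symmetrize
  ug <- sub
  for (v in seq_len(nrow(sub))) {
    pa <- which(sub[, v] == 1L)
    if (length(pa) > 1) ug[pa, pa] <- 1L
  }
  ug <- ((ug + t(ug)) > 0) * 1L
  diag(ug) <- 0L
  nodes <- rownames(sub)
  drop <- nodes %in% z
  ug[drop, ] <- 0L
  ug[, drop] <- 0L
  # connectivity from x
  seen <- rep(FALSE, nrow(ug))
  frontier <- which(nodes == x)
  while (length(frontier)) {
    seen[frontier] <- TRUE
    frontier <- which(colSums(ug[frontier, , drop = FALSE]) > 0 & !seen)
  }
  !seen[which(nodes == y)]
}

#' Serialize a DAG to JSON or Graphviz DOT
#'
#' @param g A `dag`.
#' @param path File path.
#' @return The path, invisibly (`dag_from_json()` returns the `dag`).
#' @export
dag_to_json <- function(g, path) {
  jsonlite::write_json(list(nodes = g$nodes, edges = edge_list(g)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname dag_to_json
#' @export
dag_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(raw$edges)) as.matrix(raw$edges) else NULL
  new_dag(raw$nodes, edges)
}

#' @rdname dag_to_json
#' @export
dag_to_dot <- function(g, path) {
  lines <- c("digraph bbn {", "  rankdir=LR;",
             paste0("  \"", g$nodes, "\";"),
             apply(edge_list(g), 1, function(r) {
               paste0("  \"", r[1], "\" -> \"", r[2], "\";")
             }),
             "}")
  writeLines(lines, path)
  invisible(path)
}
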