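#' PC structure learning
#'
#' Constraint-based learner: (i) adjacency (skeleton) search deleting edges
#' whose endpoints test conditionally independent, with conditioning sets
#' drawn from current neighborhoods in increasing size; (ii) collider
#' (v-structure) orientation from the recorded separating sets; (iii) Meek
#' propagation rules to closure; (iv) any remaining undirected edge oriented
#' from the lexicographically smaller label to the larger (flipped when that
#' would close a cycle) so the output is a DAG.
#'
#' @param data A `discrete_data` object.
#' @param alpha Significance level for the G-squared test (default 0.05).
#' @param max_cond Largest conditioning-set size to try (default unrestricted).
#' @param indep Optional independence oracle `function(x, y, cond)`
#'   returning TRUE when x and y are (conditionally) independent; when
#'   supplied it replaces the G-squared test, e.g. [d_separated()] on a known
#'   generating DAG for exact-recovery checks.
#' @param extend If FALSE, return the completed partially directed graph
#'   (class `pdag`) instead of extending it to a DAG.
#' @return A `dag` (or `pdag` when `extend = FALSE`) over the data's
#'   variables.
#' @export
learn_pc <- function(data, alpha = 0.05, max_cond = Inf, indep = NULL,
                     extend = TRUE) {
  labels <- colnames(data)
  p <- length(labels)
  if (is.null(indep)) {
    if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
    k <- cardinalities(data)
    if (nrow(data) < 10 * max(k)) {
      warning("fewer than 10 records per state; CI tests will be weak")
    }
    indep <- function(x, y, cond) g2_ci_test(data, x, y, cond)$p_value > alpha
  }
  adj <- matrix(TRUE, p, p, dimnames = list(labels, labels))
  diag(adj) <- FALSE
  sepsets <- list()
  sepkey <- function(a, b) paste(sort(c(a, b)), collapse = "|")

  l <- 0L
  repeat {
    any_testable <- FALSE
    pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    if (nrow(pairs)) {
      # deterministic order over label pairs
      ord <- order(labels[pairs[, 1]], labels[pairs[, 2]])
      pairs <- pairs[ord, , drop = FALSE]
    }
    for (r in seq_len(NROW(pairs))) {
      x <- labels[pairs[r, 1]]
      y <- labels[pairs[r, 2]]
      if (!adj[x, y]) next
      for (anchor in list(c(x, y), c(y, x))) {
        a <- anchor[1]; b <- anchor[2]
        nbrs <- sort(labels[adj[a, ] & labels != b])
        if (length(nbrs) < l) next
        any_testable <- TRUE
        if (l == 0L) {
          subsets <- list(character(0))
        } else {
          subsets <- utils::combn(nbrs, l, simplify = FALSE)
        }
        removed <- FALSE
        for (S in subsets) {
          if (indep(a, b, S)) {
            adj[x, y] <- adj[y, x] <- FALSE
            sepsets[[sepkey(x, y)]] <- S
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
    }
    l <- l + 1L
    if (!any_testable || l > max_cond) break
  }

  # v-structures: x - z - y with x, y nonadjacent and z not in sepset(x, y);
  # amat holds directed arcs, und the remaining undirected skeleton
  amat <- matrix(0L, p, p, dimnames = list(labels, labels))
  und <- adj
  for (z in labels) {
    nb <- labels[adj[z, ]]
    if (length(nb) < 2) next
    for (pair in utils::combn(sort(nb), 2, simplify = FALSE)) {
      x <- pair[1]; y <- pair[2]
      if (adj[x, y]) next
      S <- sepsets[[sepkey(x, y)]]
      if (!z %in% S) {
        amat[x, z] <- 1L
        amat[y, z] <- 1L
        und[x, z] <- und[z, x] <- FALSE
        und[y, z] <- und[z, y] <- FALSE
      }
    }
  }
  res <- meek_closure(amat, und)
  if (!extend) {
    return(structure(list(nodes = labels, amat = res$amat, und = res$und),
                     class = "pdag"))
  }
  extend_to_dag(labels, res$amat, res$und)
}

# Meek propagation rules R1-R3 applied to closure. amat: directed arcs;
# und: symmetric undirected adjacency. Conflicting double orientations
# (possible with imperfect tests) are resolved by keeping the first.
meek_closure <- function(amat, und) {
  labels <- rownames(amat)
  orient <- function(a, b) {
    if (amat[b, a] == 0L) amat[a, b] <<- 1L
    und[a, b] <<- und[b, a] <<- FALSE
  }
  repeat {
    changed <- FALSE
    idx <- which(und & upper.tri(und) | und & lower.tri(und), arr.ind = TRUE)
    for (r in seq_len(NROW(idx))) {
      a <- labels[idx[r, 1]]; b <- labels[idx[r, 2]]
      if (!und[a, b]) next
      # R1: c -> a - b with c, b nonadjacent  =>  a -> b
      cs <- labels[amat[, a] == 1L & !und[, a]]
      for (cc in cs) {
        if (amat[cc, b] == 0L && amat[b, cc] == 0L && !und[cc, b]) {
          orient(a, b); changed <- TRUE; break
        }
      }
      if (!und[a, b]) next
      # R2: a -> c -> b with a - b  =>  a -> b
      if (any(amat[a, ] == 1L & amat[, b] == 1L)) {
        orient(a, b); changed <- TRUE; next
      }
      # R3: a - c1 -> b, a - c2 -> b, c1 c2 nonadjacent  =>  a -> b
      cands <- labels[und[a, ] & amat[, b] == 1L]
      if (length(cands) >= 2) {
        done <- FALSE
        for (pair in utils::combn(cands, 2, simplify = FALSE)) {
          c1 <- pair[1]; c2 <- pair[2]
          if (amat[c1, c2] == 0L && amat[c2, c1] == 0L && !und[c1, c2]) {
            orient(a, b); changed <- TRUE; done <- TRUE; break
          }
        }
        if (done) next
      }
    }
    if (!changed) break
  }
  list(amat = amat, und = und)
}

# Orient leftover undirected edges lexicographically (small -> large),
# falling back to the reverse when the preferred direction closes a cycle;
# Meek rules are re-applied after each commitment.
extend_to_dag <- function(labels, amat, und) {
  repeat {
    idx <- which(und & upper.tri(und), arr.ind = TRUE)
    if (!nrow(idx)) break
    pr <- cbind(labels[idx[, 1]], labels[idx[, 2]])
    pr <- t(apply(pr, 1, sort))
    pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
    a <- pr[1, 1]; b <- pr[1, 2]
    und[a, b] <- und[b, a] <- FALSE
    if (!has_directed_path(amat, b, a)) {
      amat[a, b] <- 1L
    } else {
      amat[b, a] <- 1L
    }
    res <- meek_closure(amat, und)
    amat <- res$amat
    und <- res$und
  }
  g <- structure(list(nodes = labels, amat = amat), class = "dag")
  if (!is_acyclic(g)) {
    # conflicting collider orientations can leave a directed cycle; break it
    # by dropping the lexicographically last arc on a cycle
    g <- break_cycles(g)
  }
  g
}

break_cycles <- function(g) {
  while (!is_acyclic(g)) {
    e <- edge_list(g)
    for (r in rev(seq_len(nrow(e)))) {
      g2 <- remove_edge(g, e[r, 1], e[r, 2])
      if (has_directed_path(g2$amat, e[r, 2], e[r, 1])) {
        # this arc lies on a cycle
        g <- g2
        break
      }
    }
  }
  g
}

#' @export
print.pdag <- function(x, ...) {
  cat("Partially directed graph:", sum(x$amat), "directed,",
      sum(x$und) / 2, "undirected edges\n")
  invisible(x)
}

#' Skeleton and v-structures of a graph
#'
#' Helper views used when comparing a learned structure with the pattern of
#' a known generating DAG: `skeleton_edges()` lists unordered adjacent
#' pairs; `v_structures()` lists colliders x -> z <- y whose tails are
#' nonadjacent.
#'
#' @param g A `dag` or `pdag`.
#' @return A character matrix (possibly with zero rows).
#' @export
skeleton_edges <- function(g) {
  adj <- (g$amat + t(g$amat)) > 0
  if (!is.null(g$und)) adj <- adj | g$und
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  out <- cbind(a = g$nodes[idx[, 1]], b = g$nodes[idx[, 2]])
  if (nrow(out)) {
    out <- t(apply(out, 1, sort))
    out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  }
  out
}

#' @rdname skeleton_edges
#' @export
v_structures <- function(g) {
  adj <- (g$amat + t(g$amat)) > 0
  if (!is.null(g$und)) adj <- adj | g$und
  out <- NULL
  for (z in g$nodes) {
    pa <- g$nodes[g$amat[, z] == 1L & g$amat[z, ] == 0L]
    if (length(pa) < 2) next
    for (pair in utils::combn(sort(pa), 2, simplify = FALSE)) {
      if (!adj[pair[1], pair[2]]) {
        out <- rbind(out, c(pair[1], z, pair[2]))
      }
    }
  }
  if (is.null(out)) {
    out <- matrix(character(0), 0, 3)
  }
  colnames(out) <- c("tail1", "collider", "tail2")
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}
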