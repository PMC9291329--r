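test_that("PC with a d-separation oracle recovers canonical structures", {
  dd <- dummy_discrete(c("A", "B", "C"))
  chain <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  p <- learn_pc(dd, indep = oracle_indep(chain), extend = FALSE)
  expect_identical(skeleton_edges(p), skeleton_edges(chain))
  expect_identical(nrow(v_structures(p)), 0L)

  collider <- new_dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  p2 <- learn_pc(dd, indep = oracle_indep(collider), extend = FALSE)
  expect_identical(skeleton_edges(p2), skeleton_edges(collider))
  expect_identical(v_structures(p2), v_structures(collider))
  # extension keeps the oriented collider
  g2 <- learn_pc(dd, indep = oracle_indep(collider))
  expect_identical(unname(edge_list(g2)),
                   unname(rbind(c("A", "C"), c("B", "C"))))
})

test_that("PC with the oracle recovers skeleton and colliders on a 5-node suite", {
  labs <- LETTERS[1:5]
  dd <- dummy_discrete(labs)
  suite <- withr::with_seed(4, {
    lapply(1:25, function(i) random_dag(labs, 0.4))
  })
  suite <- c(suite,
             list(new_dag(labs),
                  new_dag(labs, cbind(labs[-5], labs[-1])),      # chain
                  new_dag(labs, cbind(labs[1:4], rep("E", 4))),  # star collider
                  new_dag(labs, t(utils::combn(labs, 2)))))      # complete
  for (g in suite) {
    p <- learn_pc(dd, indep = oracle_indep(g), extend = FALSE)
    expect_identical(skeleton_edges(p), skeleton_edges(g))
    expect_identical(v_structures(p), v_structures(g))
    ext <- learn_pc(dd, indep = oracle_indep(g))
    expect_true(is_acyclic(ext))
    expect_identical(skeleton_edges(ext), skeleton_edges(g))
  }
})

test_that("data with no separations yields a complete skeleton", {
  # three noisy copies of one binary column: every pair stays dependent
  # given the third
  withr::with_seed(7, {
    base <- sample(1:2, 800, replace = TRUE)
    flip <- function(v) ifelse(stats::runif(800) < 0.05, 3L - v, v)
    d <- new_discrete_data(cbind(a = flip(base), b = flip(base),
                                 c = flip(base)), 2)
  })
  p <- learn_pc(d, alpha = 0.05, extend = FALSE)
  expect_identical(nrow(skeleton_edges(p)), 3L)
})

test_that("BDeu matches the Polya-urn closed form and is decomposable", {
  # single binary node, counts (1, 1), ess = 1: marginal likelihood
  # 0.5 * 0.25 = 1/8, log = -3 ln 2
  d <- new_discrete_data(cbind(a = c(1L, 2L)), 2)
  g <- new_dag("a")
  expect_equal(bdeu_score(g, d), -3 * log(2))

  d3 <- withr::with_seed(12, {
    new_discrete_data(cbind(a = sample(1:2, 60, TRUE),
                            b = sample(1:3, 60, TRUE),
                            c = sample(1:2, 60, TRUE)), c(2, 3, 2))
  })
  g3 <- new_dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  total <- bdeu_score(g3, d3)
  fam <- safetybbn:::bdeu_family_score
  expect_equal(total,
               fam(d3, "a", character(0), 1) + fam(d3, "b", "a", 1) +
                 fam(d3, "c", "b", 1))
})

test_that("BDeu is likelihood-equivalent across Markov-equivalent DAGs", {
  d <- withr::with_seed(21, {
    a <- sample(1:3, 300, TRUE)
    b <- ifelse(stats::runif(300) < 0.6, a, sample(1:3, 300, TRUE))
    new_discrete_data(cbind(a = a, b = as.integer(b)), 3)
  })
  ab <- new_dag(c("a", "b"), rbind(c("a", "b")))
  ba <- new_dag(c("a", "b"), rbind(c("b", "a")))
  expect_equal(bdeu_score(ab, d), bdeu_score(ba, d), tolerance = 1e-10)

  # covered edge reversals on random 4-node DAGs preserve the score
  labs <- letters[1:4]
  dat <- withr::with_seed(22, {
    new_discrete_data(matrix(sample(1:3, 4 * 200, TRUE), 200, 4,
                             dimnames = list(NULL, labs)), 3)
  })
  dags <- withr::with_seed(23, lapply(1:10, function(i) random_dag(labs, 0.5)))
  checked <- 0L
  for (g in dags) {
    e <- edge_list(g)
    for (r in seq_len(nrow(e))) {
      x <- e[r, 1]; y <- e[r, 2]
      if (setequal(parents(g, y), c(parents(g, x), x))) { # covered edge
        g2 <- safetybbn:::add_edge(safetybbn:::remove_edge(g, x, y), y, x)
        expect_equal(bdeu_score(g, dat), bdeu_score(g2, dat),
                     tolerance = 1e-9)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 0L)
})

test_that("GTT finds single-arc dependence and stays empty on noise", {
  ind <- withr::with_seed(41, {
    new_discrete_data(matrix(sample(1:3, 3 * 800, TRUE), 800, 3,
                             dimnames = list(NULL, c("a", "b", "c"))), 3)
  })
  g0 <- learn_gtt(ind)
  expect_identical(n_edges(g0), 0L)

  dep <- withr::with_seed(42, {
    a <- sample(1:3, 5000, TRUE)
    b <- ifelse(stats::runif(5000) < 0.7, a, sample(1:3, 5000, TRUE))
    new_discrete_data(cbind(a = a, b = as.integer(b)), 3)
  })
  g1 <- learn_gtt(dep)
  expect_identical(n_edges(g1), 1L)
  expect_true(all(sort(skeleton_edges(g1)) == c("a", "b")))
  # direct-evaluation oracle: the returned structure scores at least as
  # well as all three candidates
  cands <- list(new_dag(c("a", "b")),
                new_dag(c("a", "b"), rbind(c("a", "b"))),
                new_dag(c("a", "b"), rbind(c("b", "a"))))
  best <- max(vapply(cands, bdeu_score, numeric(1), data = dep))
  expect_equal(attr(g1, "score"), best, tolerance = 1e-9)
})

test_that("greedy score trajectories are monotone and outputs acyclic", {
  tab <- calibrated_survey(413, seed = 6)
  d <- apply_scheme(fit_uniform_width(tab, 3), tab)
  for (g in list(learn_gtt(d), learn_bayesian_search(d, restarts = 3,
                                                     seed = 6))) {
    expect_true(is_acyclic(g))
    expect_true(all(diff(attr(g, "score_trace")) > 0))
    expect_equal(attr(g, "score"), bdeu_score(g, d), tolerance = 1e-8)
  }
})

test_that("Bayesian search is seeded, bounded below, and finds true nets", {
  ind <- withr::with_seed(51, {
    new_discrete_data(matrix(sample(1:2, 3 * 500, TRUE), 500, 3,
                             dimnames = list(NULL, c("a", "b", "c"))), 2)
  })
  g <- learn_bayesian_search(ind, restarts = 1, seed = 1)
  expect_identical(n_edges(g), 0L) # no improving move from the empty graph

  labs <- letters[1:4]
  truth <- new_dag(labs, rbind(c("a", "b"), c("b", "c"), c("b", "d")))
  dat <- withr::with_seed(52, {
    n <- 5000
    noisy <- function(p) as.integer(ifelse(stats::runif(n) < 0.75, p,
                                           sample(1:3, n, TRUE)))
    a <- sample(1:3, n, TRUE)
    b <- noisy(a)
    new_discrete_data(cbind(a = a, b = b, c = noisy(b), d = noisy(b)), 3)
  })
  res <- learn_bayesian_search(dat, restarts = 5, seed = 2)
  expect_gte(attr(res, "score"), bdeu_score(truth, dat) - 1e-9)
  expect_gte(attr(res, "score"), bdeu_score(new_dag(labs), dat))
  r2 <- learn_bayesian_search(dat, restarts = 5, seed = 2)
  expect_identical(edge_list(res), edge_list(r2))
})
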