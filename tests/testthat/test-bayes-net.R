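test_that("CPT fitting smooths, normalizes, and matches hand counts", {
  # single binary node, counts (3, 1), maximum likelihood
  d <- new_discrete_data(cbind(a = c(1L, 1L, 1L, 2L)), 2)
  net0 <- fit_cpts(new_dag("a"), d, alpha = 0)
  expect_equal(as.numeric(net0$cpts$a$prob), c(0.75, 0.25))

  # unobserved parent combination under alpha = 1 gives a uniform row
  d2 <- new_discrete_data(cbind(p = c(1L, 1L, 2L, 2L),
                                c = c(1L, 3L, 2L, 2L)), 3)
  g2 <- new_dag(c("p", "c"), rbind(c("p", "c")))
  net2 <- fit_cpts(g2, d2, alpha = 1)
  expect_equal(net2$cpts$c$prob[3, ], rep(1 / 3, 3)) # p = 3 never observed
  expect_true(all(abs(rowSums(net2$cpts$c$prob) - 1) < 1e-9))
  expect_error(fit_cpts(g2, d2, alpha = 0), "unobserved")
})

test_that("joint probabilities follow the chain rule", {
  net <- manual_net(
    c("a", "b"), NULL,
    list(a = list(parents = character(0),
                  prob = matrix(c(0.5, 0.5), 1)),
         b = list(parents = character(0),
                  prob = matrix(c(0.2, 0.8), 1))), 2)
  expect_equal(joint_probability(net, c(a = 1L, b = 2L)), 0.4)

  ab <- manual_net(
    c("a", "b"), rbind(c("a", "b")),
    list(a = list(parents = character(0),
                  prob = matrix(c(0.3, 0.7), 1)),
         b = list(parents = "a",
                  prob = rbind(c(0.4, 0.6), c(0.9, 0.1)))), 2)
  expect_equal(joint_probability(ab, c(a = 1L, b = 2L)), 0.3 * 0.6)
  expect_error(joint_probability(ab, c(a = 1L)), "every node")

  # normalization over all assignments of a fitted 9-variable net
  tab <- calibrated_survey(413, seed = 13)
  disc <- apply_scheme(fit_uniform_width(tab, 3), tab)
  net9 <- fit_cpts(learn_pc(disc), disc)
  ej <- enum_joint(net9)
  expect_equal(sum(ej$p), 1, tolerance = 1e-9)
})

test_that("posteriors on a hand-built collider match Bayes-rule inversion", {
  # a, b independent coins; c = collider with known CPT
  net <- manual_net(
    c("a", "b", "c"), rbind(c("a", "c"), c("b", "c")),
    list(a = list(parents = character(0), prob = matrix(c(0.6, 0.4), 1)),
         b = list(parents = character(0), prob = matrix(c(0.3, 0.7), 1)),
         c = list(parents = c("a", "b"),
                  prob = rbind(c(0.9, 0.1), c(0.5, 0.5),
                               c(0.4, 0.6), c(0.2, 0.8)))), 2)
  post <- posterior_marginals(net, c(c = 2L))
  ref <- enum_marginals(net, c(c = 2L))
  for (v in c("a", "b", "c")) expect_equal(post[[v]], ref[[v]],
                                           tolerance = 1e-12)
  expect_equal(attr(post, "p_evidence"), attr(ref, "p_evidence"),
               tolerance = 1e-12)
})

test_that("variable elimination equals enumeration on random 3-state nets", {
  labs <- paste0("v", 1:9)
  withr::with_seed(61, {
    for (i in 1:10) {
      net <- random_net(labs, k = 3L, p_edge = 0.3)
      ev_n <- sample(0:3, 1)
      ev <- integer(0)
      if (ev_n > 0) {
        who <- sample(labs, ev_n)
        ev <- stats::setNames(sample(1:3, ev_n, TRUE), who)
      }
      ve <- posterior_marginals(net, ev)
      en <- enum_marginals(net, ev)
      for (v in labs) expect_equal(ve[[v]], en[[v]], tolerance = 1e-9)
      expect_true(all(abs(vapply(ve, sum, numeric(1)) - 1) < 1e-9))
    }
  })
})

test_that("evidence handling is consistent", {
  labs <- paste0("v", 1:5)
  net <- withr::with_seed(62, random_net(labs, 3L, 0.4))
  pri <- posterior_marginals(net)
  # empty evidence reproduces priors; point evidence pins the node
  ev <- c(v2 = 3L)
  post <- posterior_marginals(net, ev)
  expect_equal(post$v2, c(0, 0, 1))
  # conditioning on an (almost) certain event leaves marginals unchanged
  det <- manual_net(
    c("a", "b"), rbind(c("a", "b")),
    list(a = list(parents = character(0), prob = matrix(c(1, 0), 1)),
         b = list(parents = "a", prob = rbind(c(0.3, 0.7), c(0.5, 0.5)))), 2)
  same <- posterior_marginals(det, c(a = 1L))
  base <- posterior_marginals(det)
  expect_equal(same$b, base$b, tolerance = 1e-9)
  # zero-probability evidence errors out
  expect_error(posterior_marginals(det, c(a = 2L)), "zero probability")
  expect_error(posterior_marginals(net, c(bogus = 1L)), "nodes")
})

test_that("MAP prediction selects the posterior mode with low-state ties", {
  # target copies the factor through a deterministic CPT
  copynet <- manual_net(
    c("f", "t"), rbind(c("f", "t")),
    list(f = list(parents = character(0), prob = matrix(rep(1 / 3, 3), 1)),
         t = list(parents = "f", prob = diag(3))), 3)
  for (s in 1:3) {
    expect_equal(as.integer(predict_map(copynet, c(f = s), "t")), s)
  }
  # uniform target independent of evidence: tie broken toward state 1
  unif <- manual_net(
    c("f", "t"), NULL,
    list(f = list(parents = character(0), prob = matrix(rep(1 / 3, 3), 1)),
         t = list(parents = character(0), prob = matrix(rep(1 / 3, 3), 1))), 3)
  expect_equal(as.integer(predict_map(unif, c(f = 2L), "t")), 1L)
  # posterior (0.2, 0.5, 0.3) predicts state 2
  net2 <- manual_net(
    c("f", "t"), rbind(c("f", "t")),
    list(f = list(parents = character(0), prob = matrix(c(1, 0, 0), 1)),
         t = list(parents = "f", prob = rbind(c(0.2, 0.5, 0.3),
                                              c(1, 0, 0), c(1, 0, 0)))), 3)
  expect_equal(as.integer(predict_map(net2, c(f = 1L), "t")), 2L)
  expect_error(predict_map(net2, c(x = 1L), "t"), "cover")
})

test_that("networks survive a JSON round trip losslessly", {
  tab <- calibrated_survey(200, seed = 17)
  disc <- apply_scheme(fit_uniform_width(tab, 3), tab)
  net <- fit_cpts(learn_gtt(disc), disc)
  path <- withr::local_tempfile(fileext = ".json")
  net_to_json(net, path)
  back <- net_from_json(path)
  expect_identical(edge_list(back$dag), edge_list(net$dag))
  expect_equal(back$k, net$k)
  for (v in net$dag$nodes) {
    expect_identical(back$cpts[[v]]$parents, net$cpts[[v]]$parents)
    expect_equal(back$cpts[[v]]$prob, net$cpts[[v]]$prob, tolerance = 1e-12)
  }
  # inference agrees after the round trip
  expect_equal(posterior_marginals(back), posterior_marginals(net),
               tolerance = 1e-12)
})
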