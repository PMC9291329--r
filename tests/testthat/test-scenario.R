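test_that("backward propagation leaves an edgeless net unchanged", {
  net <- manual_net(
    c("f", "t"), NULL,
    list(f = list(parents = character(0), prob = matrix(c(0.2, 0.3, 0.5), 1)),
         t = list(parents = character(0), prob = matrix(c(0.1, 0.6, 0.3), 1))),
    3)
  bp <- backward_propagation(net, "t", 3L)
  expect_equal(unname(bp$change["f"]), 0)
  expect_equal(bp$posteriors$f, bp$priors$f)
})

test_that("backward propagation matches Bayes-rule inversion on two nodes", {
  net <- manual_net(
    c("f", "t"), rbind(c("f", "t")),
    list(f = list(parents = character(0), prob = matrix(c(0.25, 0.75), 1)),
         t = list(parents = "f", prob = rbind(c(0.8, 0.2), c(0.3, 0.7)))), 2)
  bp <- backward_propagation(net, "t", 1L)
  # hand inversion: P(f=1 | t=1) = .25*.8 / (.25*.8 + .75*.3)
  p_f1 <- 0.25 * 0.8 / (0.25 * 0.8 + 0.75 * 0.3)
  expect_equal(bp$posteriors$f, c(p_f1, 1 - p_f1), tolerance = 1e-12)
  # total-variation change agrees with the enumeration oracle
  en <- enum_marginals(net, c(t = 1L))
  expect_equal(unname(bp$change["f"]),
               sum(abs(en$f - enum_marginals(net)$f)) / 2, tolerance = 1e-12)
})

test_that("zero-probability target states raise an explicit error", {
  net <- manual_net(
    c("f", "t"), rbind(c("f", "t")),
    list(f = list(parents = character(0), prob = matrix(c(1, 0), 1)),
         t = list(parents = "f", prob = rbind(c(1, 0), c(0.5, 0.5)))), 2)
  expect_error(backward_propagation(net, "t", 2L), "zero probability")
})

test_that("impact deltas match the hand mixture computation", {
  # uniform 3-state factor; P(t = worst | f) = .6, .2, .1
  net <- manual_net(
    c("f", "t"), rbind(c("f", "t")),
    list(f = list(parents = character(0), prob = matrix(rep(1 / 3, 3), 1)),
         t = list(parents = "f", prob = rbind(c(0.4, 0.6), c(0.8, 0.2),
                                              c(0.9, 0.1)))), c(3, 2))
  imp <- impact_assessment(net, "t", worst_target_state = 2L)
  expect_equal(attr(imp, "baseline"), 0.3, tolerance = 1e-12)
  expect_equal(imp$delta_s1, 30, tolerance = 1e-9)
  expect_equal(imp$delta_s3, -20, tolerance = 1e-9)
  # mixture consistency: baseline = sum_s P(f=s) P(t=worst | f=s)
  pri <- posterior_marginals(net)
  mix <- sum(pri$f * c(0.6, 0.2, 0.1))
  expect_equal(attr(imp, "baseline"), mix, tolerance = 1e-9)
})

test_that("a d-separated factor has zero impact", {
  net <- manual_net(
    c("f", "g", "t"), rbind(c("g", "t")),
    list(f = list(parents = character(0), prob = matrix(c(0.5, 0.5), 1)),
         g = list(parents = character(0), prob = matrix(c(0.4, 0.6), 1)),
         t = list(parents = "g", prob = rbind(c(0.9, 0.1), c(0.2, 0.8)))), 2)
  imp <- impact_assessment(net, "t", worst_target_state = 2L)
  f_row <- imp[imp$factor == "f", ]
  expect_equal(f_row$delta_s1, 0, tolerance = 1e-9)
  expect_equal(f_row$delta_s3, 0, tolerance = 1e-9)
})

test_that("impact deltas agree with enumeration on random nets", {
  labs <- paste0("v", 1:6)
  withr::with_seed(81, {
    for (i in 1:5) {
      net <- random_net(labs, 3L, 0.35)
      imp <- impact_assessment(net, "v6")
      pri <- enum_marginals(net)
      for (f in setdiff(labs, "v6")) {
        en1 <- enum_marginals(net, stats::setNames(1L, f))
        en3 <- enum_marginals(net, stats::setNames(3L, f))
        base <- pri$v6[3]
        expect_equal(imp$delta_s1[imp$factor == f], 100 * (en1$v6[3] - base),
                     tolerance = 1e-9)
        expect_equal(imp$delta_s3[imp$factor == f], 100 * (en3$v6[3] - base),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("negative factor-target dependence gives signed deltas", {
  # calibrated pipeline: worst factor band raises the error probability,
  # best band lowers it, for the strongly correlated factors
  hits <- vapply(1:5, function(seed) {
    tab <- calibrated_survey(413, seed = 100 + seed)
    disc <- apply_scheme(fit_uniform_width(tab, 3), tab)
    net <- fit_cpts(learn_pc(disc), disc)
    imp <- impact_assessment(net, "patient_safety_errors")
    strong <- imp$factor %in% c("health_wellbeing", "safe_environment_bh")
    all(imp$delta_s1[strong] >= 0) && all(imp$delta_s3[strong] <= 0)
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("ranking uses tie-averaged ranks with invariant rank sums", {
  imp <- structure(data.frame(factor = c("a", "b", "c"),
                              delta_s1 = c(35, 26, 5),
                              delta_s3 = c(-10, -20, -5)),
                   baseline = 0.13,
                   class = c("impact_assessment", "data.frame"))
  v <- rank_factors(imp, "vulnerability")
  expect_equal(v$rank, c(1, 2, 3))
  r <- rank_factors(imp, "resilience")
  expect_equal(r$rank, c(2, 1, 3))

  tied <- structure(data.frame(factor = letters[1:8],
                               delta_s1 = c(35, 26, 20, 8, 8, 6, 5, 1),
                               delta_s3 = rep(-4, 8)),
                    baseline = 0.13,
                    class = c("impact_assessment", "data.frame"))
  vt <- rank_factors(tied, "vulnerability")
  expect_equal(vt$rank[4:5], c(4.5, 4.5)) # equal deltas share positions 4, 5
  expect_equal(sum(vt$rank), 8 * 9 / 2)
  rt <- rank_factors(tied, "resilience")
  expect_equal(rt$rank, rep(4.5, 8)) # full tie: everyone gets (m+1)/2
})

test_that("rank correlation is tie-corrected Pearson on ranks", {
  mk <- function(rk) data.frame(factor = paste0("f", seq_along(rk)), rank = rk)
  expect_equal(spearman_rank_corr(mk(1:8), mk(1:8)), 1)
  expect_equal(spearman_rank_corr(mk(1:8), mk(8:1)), -1)
  # tie-free inputs reduce to the classical 1 - 6 sum d^2 / (m^3 - m)
  a <- c(3, 1, 4, 2, 5); b <- c(2, 3, 5, 1, 4)
  d2 <- sum((a - b)^2)
  expect_equal(spearman_rank_corr(mk(a), mk(b)),
               1 - 6 * d2 / (125 - 5), tolerance = 1e-12)
  expect_error(spearman_rank_corr(mk(rep(1, 4)), mk(1:4)), "zero variance")
  expect_error(spearman_rank_corr(mk(1:3), mk(1:4)), "same factors")
})
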