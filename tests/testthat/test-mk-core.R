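t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("transition matrix follows the two-state closed form", {
  expect_equal(transition_matrix(5, 0), diag(2), ignore_attr = TRUE)
  big <- transition_matrix(1, 1e6)
  expect_equal(as.vector(big), rep(0.5, 4), tolerance = 1e-12)
  expect_equal(transition_matrix(1, 1)[1, 1], 0.5 * (1 + exp(-2)))
  P <- transition_matrix(0.3, 1.7)
  expect_equal(rowSums(P), c("0" = 1, "1" = 1))
  expect_equal(P, t(P))
  expect_error(transition_matrix(-1, 1), "non-negative")
})

test_that("pruning likelihood matches exhaustive enumeration", {
  ll <- pruning_likelihood(t3, c(A = 1, B = 1, C = 0), er_model(0.5))
  expect_equal(ll$loglik,
               log(oracle_lik(t3, c(A = 1, B = 1, C = 0), 0.5)),
               tolerance = 1e-10)
  # degenerate cases
  expect_equal(pruning_likelihood(
    ape::read.tree(text = "(A:1,B:1);"),
    c(A = NA, B = NA), er_model(0.8))$loglik, 0)
  expect_equal(pruning_likelihood(
    ape::read.tree(text = "(A:1,B:1);"),
    c(A = 1, B = 1), er_model(0))$loglik, log(0.5))
  # missing data marginalized
  s <- c(A = 1, B = NA, C = 0)
  expect_equal(pruning_likelihood(t3, s, er_model(1.3))$loglik,
               log(oracle_lik(t3, s, 1.3)), tolerance = 1e-10)
  expect_error(pruning_likelihood(t3, c(A = 1, B = 1), er_model(1)),
               "mismatch")
})

test_that("likelihood is invariant under rate/branch-length rescaling", {
  set.seed(3)
  tr <- ape::rtree(6)
  s <- random_states(tr, 0.1)
  base <- pruning_likelihood(tr, s, er_model(0.7))$loglik
  for (cc in c(0.1, 3, 25)) {
    tr2 <- tr
    tr2$edge.length <- tr$edge.length / cc
    expect_equal(pruning_likelihood(tr2, s, er_model(0.7 * cc))$loglik,
                 base, tolerance = 1e-9)
  }
})

test_that("ascertainment correction excludes exactly the all-zero mass", {
  m <- er_model(0.5)
  # zero-rate: P(all zero) = prior mass on 0
  expect_equal(ascertainment_prob(t3, er_model(0), t3$tip.label), 0.5)
  # independence limit: huge rate decouples tips
  expect_equal(ascertainment_prob(t3, er_model(1e8), t3$tip.label),
               0.5^3, tolerance = 1e-6)
  expect_equal(ascertainment_prob(t3, m, t3$tip.label),
               oracle_all_zero(t3, 0.5, t3$tip.label), tolerance = 1e-12)
  # with a missing tip, only observed tips are conditioned on
  expect_equal(ascertainment_prob(t3, m, c("A", "C")),
               oracle_all_zero(t3, 0.5, c("A", "C")), tolerance = 1e-12)
  # corrected pattern probabilities over non-all-zero patterns sum to 1
  pats <- all_patterns(3)
  p0 <- oracle_all_zero(t3, 0.5, t3$tip.label)
  tot <- 0
  for (r in seq_len(nrow(pats))) {
    if (all(pats[r, ] == 0)) next
    s <- setNames(pats[r, ], t3$tip.label)
    tot <- tot + exp(pruning_likelihood(t3, s, m,
                                        ascertainment = "no_all_zero")$loglik)
  }
  expect_equal(tot, 1, tolerance = 1e-10)
  expect_equal(exp(pruning_likelihood(t3, c(A = 1, B = 1, C = 0), m,
                                      "no_all_zero")$loglik),
               oracle_lik(t3, c(A = 1, B = 1, C = 0), 0.5) / (1 - p0),
               tolerance = 1e-12)
})

test_that("rate fitting agrees with a dense grid search", {
  s <- c(A = 1, B = 1, C = 0)
  f <- fit_rate(t3, s, ascertainment = "none")
  # two-stage grid at 1e-4 final resolution in log q
  grid1 <- seq(f$bounds[1], f$bounds[2], length.out = 400)
  ll1 <- vapply(grid1, function(lq)
    pruning_likelihood(t3, s, er_model(exp(lq)))$loglik, 0)
  c1 <- grid1[which.max(ll1)]
  grid2 <- seq(c1 - 0.05, c1 + 0.05, by = 1e-4)
  ll2 <- vapply(grid2, function(lq)
    pruning_likelihood(t3, s, er_model(exp(lq)))$loglik, 0)
  expect_equal(log(f$model$q), grid2[which.max(ll2)], tolerance = 2e-4)
  expect_equal(f$loglik, max(ll2), tolerance = 1e-8)

  fc <- fit_rate(t3, s, ascertainment = "no_all_zero")
  llc <- vapply(grid2, function(lq)
    pruning_likelihood(t3, s, er_model(exp(lq)), "no_all_zero")$loglik, 0)
  expect_gte(fc$loglik + 1e-8, max(llc))
})

test_that("degenerate characters behave as documented", {
  expect_error(fit_rate(t3, c(A = 0, B = 0, C = 0)), "unobservable")
  expect_error(fit_rate(t3, c(A = NA, B = NA, C = NA)), "missing")
  f1 <- fit_rate(t3, c(A = 1, B = 1, C = 1))
  expect_equal(log(f1$model$q), f1$bounds[1], tolerance = 1e-4)
  expect_gt(f1$root_p1, 0.999)
})

test_that("marginal root probability matches enumeration and symmetry", {
  s <- c(A = 1, B = 1, C = 0)
  m <- er_model(0.5)
  expect_equal(marginal_root(t3, s, m),
               oracle_marginal(t3, s, 0.5, 4L), tolerance = 1e-10)
  expect_equal(marginal_root(t3, c(A = NA, B = NA, C = NA), m), 0.5)
  # ER + equal prior: complement data flips the root probability
  set.seed(5)
  for (i in 1:20) {
    tr <- ape::rtree(5)
    st <- random_states(tr)
    if (all(is.na(st))) next
    q <- runif(1, 0.05, 3)
    p1 <- marginal_root(tr, st, er_model(q))
    p2 <- marginal_root(tr, 1L - st, er_model(q))
    expect_equal(p1 + p2, 1, tolerance = 1e-12)
  }
})

test_that("marginal root is unchanged by the ascertainment flag", {
  # the correction divides both root partial terms equally and cancels;
  # fitted-rate pipelines therefore only feel the flag through q-hat
  s <- c(A = 1, B = NA, C = 0)
  for (q in c(0.1, 0.9, 4)) {
    pl_none <- pruning_likelihood(t3, s, er_model(q), "none")
    pl_asc <- pruning_likelihood(t3, s, er_model(q), "no_all_zero")
    r1 <- pl_none$root_partials[2] / sum(pl_none$root_partials)
    r2 <- pl_asc$root_partials[2] / sum(pl_asc$root_partials)
    expect_identical(r1, r2)
    expect_equal(marginal_root(t3, s, er_model(q)), r1, tolerance = 1e-12)
  }
})

test_that("internal-node marginals match enumeration on a 4-tip tree", {
  t4 <- ape::read.tree(text = "((A:0.4,B:0.9):0.5,(C:1.2,D:0.3):0.8);")
  s <- c(A = 1, B = 0, C = 1, D = NA)
  m <- er_model(0.7)
  ms <- marginal_states(t4, s, m)
  expect_equal(rowSums(ms), rep(1, nrow(ms)), ignore_attr = TRUE)
  for (node in 5:7)
    expect_equal(unname(ms[node, "p1"]),
                 oracle_marginal(t4, s, 0.7, node), tolerance = 1e-9)
  expect_equal(unname(ms[5, "p1"]), marginal_root(t4, s, m),
               tolerance = 1e-12)
  expect_equal(marginal_states(t4, s, m, node = 5), ms[5, ])
  expect_error(marginal_states(t4, s, m, node = 99), "unknown node")
  # both tips below a node present, tiny rate: near-certain presence
  ms2 <- marginal_states(t4, c(A = 1, B = 1, C = 0, D = 0),
                         er_model(0.01))
  expect_gt(ms2[6, "p1"], 0.99)
})

test_that("single-character and pooled rate recovery from simulation", {
  cfg <- sim_config(seed = 21, n_trees = 1, height_jitter = 0, q = 0.5,
                    n_characters = 200, elfdalian_na = FALSE)
  tr <- simulate_trees(cfg)[[1]]
  sim <- simulate_traits(tr, cfg)
  keep <- colSums(sim$tip_states, na.rm = TRUE) > 0
  qs <- apply(sim$tip_states[, keep], 2, function(col) {
    fit_rate(tr, setNames(col, rownames(sim$tip_states)))$model$q
  })
  expect_lt(abs(log(median(qs) / 0.5)), log(3))
  pooled <- fit_rate_pooled(tr, sim$tip_states[, keep])
  expect_lt(abs(pooled$q - 0.5) / 0.5, 0.2)
})

test_that("fitted ER log-likelihood agrees with an independent fitter", {
  skip_if_not_installed("phytools")
  f <- fit_rate(t3, c(A = 1, B = 1, C = 0), ascertainment = "none")
  pf <- phytools::fitMk(t3, setNames(c("1", "1", "0"), c("A", "B", "C")),
                        model = "ER", pi = c(0.5, 0.5))
  expect_equal(f$model$q, unname(pf$rates), tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(stats::logLik(pf)), tolerance = 1e-6)
})
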