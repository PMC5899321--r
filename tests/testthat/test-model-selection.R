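# Cross-validation splits, predictive scores, and paired comparisons.

test_that("cv splits follow both schemes and stay disjoint", {
  sp <- make_cv_splits(66593, fractions = c(0.9, 0.1), replicates = 10,
                       seed = 2)
  expect_length(sp, 10L)
  expect_true(all(vapply(sp, function(s) length(s$train) == 59934,
                         logical(1))))
  expect_true(all(vapply(sp, function(s) length(s$test) == 6659,
                         logical(1))))
  sp2 <- make_cv_splits(66593, train = 10000, test = 2000, replicates = 10,
                        seed = 2)
  for (s in sp2) {
    expect_length(s$train, 10000L)
    expect_length(s$test, 2000L)
    expect_length(intersect(s$train, s$test), 0L)
    expect_true(all(c(s$train, s$test) %in% seq_len(66593)))
  }
  expect_identical(make_cv_splits(100, train = 50, test = 10, seed = 7),
                   make_cv_splits(100, train = 50, test = 10, seed = 7))
  expect_error(make_cv_splits(100, train = 90, test = 20), "exceeds")
})

test_that("predictive score reduces to the plain log-likelihood at S = 1", {
  set.seed(81)
  tr <- ape::rtree(4)
  dat <- matrix(sample(aa_states(), 4 * 30, replace = TRUE), 4, 30,
                dimnames = list(tr$tip.label, NULL))
  mod <- aa_model("poisson", alpha = 1, ncat = 2L)
  trace1 <- posterior_trace(
    "phylogram",
    data.frame(cycle = 1L, lnL = 0, lnPrior = 0, alpha = 1,
               tree_length = sum(tr$edge.length), n_comp = 1L),
    trees = list(tr), models = list(mod),
    config = chain_config(1, thin = 1, burnin = 0, seed = 1), model = mod)
  sc <- cv_predictive_score(trace1, dat)
  expect_equal(sc, pruning_loglik(tr, dat, mod), tolerance = 1e-12)

  # duplicated sample set gives the identical score
  trace2 <- trace1
  trace2$scalars <- rbind(trace1$scalars, trace1$scalars)
  trace2$trees <- c(trace1$trees, trace1$trees)
  trace2$models <- c(trace1$models, trace1$models)
  expect_equal(cv_predictive_score(trace2, dat), sc, tolerance = 1e-12)

  # additive over independent test sites at S = 1
  expect_equal(sc, cv_predictive_score(trace1, dat[, 1:10]) +
                 cv_predictive_score(trace1, dat[, 11:30]),
               tolerance = 1e-10)
  # invariant to test-site ordering
  perm <- sample(30)
  expect_equal(cv_predictive_score(trace1, dat[, perm]), sc,
               tolerance = 1e-12)
})

test_that("predictive score matches the direct summation oracle", {
  set.seed(82)
  trees <- replicate(4, ape::rtree(4, tip.label = c("A", "B", "C", "D")),
                     simplify = FALSE)
  dat <- matrix(sample(aa_states(), 4 * 20, replace = TRUE), 4, 20,
                dimnames = list(c("A", "B", "C", "D"), NULL))
  mods <- lapply(c(0.5, 1, 2, 4), function(a) aa_model("lg", alpha = a))
  trace <- posterior_trace(
    "phylogram",
    data.frame(cycle = 1:4, lnL = 0, lnPrior = 0,
               alpha = c(0.5, 1, 2, 4), tree_length = 1, n_comp = 1L),
    trees = trees, models = mods,
    config = chain_config(4, thin = 1, burnin = 0, seed = 1),
    model = mods[[1]])
  sc <- cv_predictive_score(trace, dat)
  lls <- vapply(1:4, function(s) pruning_loglik(trees[[s]], dat, mods[[s]]),
                numeric(1))
  oracle <- log(mean(exp(lls - max(lls)))) + max(lls)
  expect_equal(sc, oracle, tolerance = 1e-10)
})

test_that("paired model comparison summarizes score differences", {
  cmp0 <- compare_models(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp0$mean, 0)
  expect_equal(cmp0$sd, 0)
  cmp <- compare_models(c(5, 7, 9), c(1, 2, 3))
  expect_equal(cmp$delta, c(4, 5, 6))
  expect_equal(cmp$mean, 5)
  expect_equal(cmp$sd, 1)
  expect_equal(cmp$wins, 3L)
  expect_error(compare_models(1:3, 1:4), "unpaired")
})

test_that("cv prefers the generating model over a misspecified one (small run)", {
  set.seed(83)
  # data from a non-uniform-frequency model; compare LG-frequency vs
  # uniform-frequency (Poisson) fits with fixed parameters at S = 1-style
  # traces from short learning runs
  lg <- chronoforge:::.empirical_model("lg")
  tr <- ape::rtree(5)
  tr$edge.length <- tr$edge.length * 0.3
  gen <- aa_model("lg", alpha = 1, ncat = 1L)
  ages <- NULL
  dat <- local({
    # simulate directly on the phylogram: unit-rate clock over its depths
    nst <- 500
    sim <- matrix("", 5, nst, dimnames = list(tr$tip.label, NULL))
    eig <- chronoforge:::.eigen_q(build_rate_matrix(gen$rho, gen$freqs),
                                  gen$freqs)
    root_states <- sample.int(20, nst, TRUE, prob = gen$freqs)
    states <- matrix(0L, 5 + tr$Nnode, nst)
    states[6, ] <- root_states
    for (v in chronoforge:::.preorder_nodes(tr)) {
      if (v == 6) next
      e <- match(v, tr$edge[, 2])
      P <- chronoforge:::.prob_matrix(eig, tr$edge.length[e])
      P <- P / rowSums(P)
      for (a in unique(states[tr$edge[e, 1], ])) {
        ii <- which(states[tr$edge[e, 1], ] == a)
        states[v, ii] <- sample.int(20, length(ii), TRUE, prob = P[a, ])
      }
    }
    matrix(aa_states()[states[1:5, ]], 5, nst,
           dimnames = list(tr$tip.label, NULL))
  })
  splits <- make_cv_splits(500, train = 300, test = 100, replicates = 3,
                           seed = 84)
  wins <- 0L
  for (s in splits) {
    cfg <- chain_config(120, thin = 2, burnin = 20, seed = 85 + s$id)
    tA <- run_phylogram_chain(dat[, s$train], aa_model("lg", ncat = 1L),
                              cfg, sample_topology = FALSE, start_tree = tr,
                              estimate_alpha = FALSE)
    tB <- run_phylogram_chain(dat[, s$train], aa_model("poisson", ncat = 1L),
                              cfg, sample_topology = FALSE, start_tree = tr,
                              estimate_alpha = FALSE)
    sa <- cv_predictive_score(trace_retained(tA), dat[, s$test])
    sb <- cv_predictive_score(trace_retained(tB), dat[, s$test])
    if (sa > sb) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
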