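# Sampler mechanics: determinism, proposal validity, prior sampling,
# posterior concentration, and convergence reporting.

test_that("chain configuration enforces the bookkeeping arithmetic", {
  cfg <- chain_config(6000, thin = 1, burnin = 1000)
  expect_equal(floor(cfg$cycles / cfg$thin) - cfg$burnin, 5000L)
  expect_error(chain_config(100, thin = 1, burnin = 100), "burn-in")
  expect_error(chain_config(0), "cycles")
})

test_that("retained samples and multi-chain pooling match the schedule", {
  tr <- parse_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  cfg <- chain_config(60, thin = 1, burnin = 10, seed = 4)
  traces <- lapply(1:2, function(i) {
    run_dating_chain(tr, likelihood_off = TRUE,
                     clock = clock_model("cl", mu_r = 1e-3),
                     config = cfg, chain_id = i)
  })
  retained <- lapply(traces, trace_retained)
  expect_equal(nrow(retained[[1]]$scalars), 50L)
  expect_equal(sum(vapply(retained, function(x) nrow(x$scalars), numeric(1))),
               100L)
  expect_error(trace_retained(traces[[1]], burnin = 60), "shorter")
})

test_that("identical seeds give bitwise-identical traces", {
  set.seed(99)  # must not matter
  b <- make_benchmark("tiny", seed = 3)
  dat <- b$supermatrix$matrix[, 1:120]
  cfg <- chain_config(15, thin = 1, burnin = 2, seed = 11)
  t1 <- run_phylogram_chain(dat, aa_model("poisson", ncat = 1L), cfg)
  t2 <- run_phylogram_chain(dat, aa_model("poisson", ncat = 1L), cfg)
  expect_identical(t1$scalars, t2$scalars)
  expect_identical(lapply(t1$trees, write_newick),
                   lapply(t2$trees, write_newick))
  t3 <- run_phylogram_chain(dat, aa_model("poisson", ncat = 1L),
                            chain_config(15, thin = 1, burnin = 2, seed = 12))
  expect_false(identical(t1$scalars$lnL, t3$scalars$lnL))
})

test_that("NNI proposals hit the alternative resolutions uniformly", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  set.seed(17)
  counts <- c(`A,C` = 0L, `A,D` = 0L, same = 0L)
  tips_ok <- TRUE
  for (i in 1:2000) {
    prop <- chronoforge:::.nni_propose(tr)$tree
    keys <- chronoforge:::.clade_keys(prop)
    if ("A\rC" %in% keys || "B\rD" %in% keys) {
      counts[["A,C"]] <- counts[["A,C"]] + 1L
    } else if ("A\rD" %in% keys || "B\rC" %in% keys) {
      counts[["A,D"]] <- counts[["A,D"]] + 1L
    } else counts[["same"]] <- counts[["same"]] + 1L
    tips_ok <- tips_ok && setequal(prop$tip.label, tr$tip.label)
  }
  expect_true(tips_ok)
  # the two alternative unrooted resolutions are proposed equally often
  expect_gt(chisq.test(counts[1:2])$p.value, 0.001)
  expect_gt(min(counts[1:2]), 0)
})

test_that("SPR proposals preserve tree validity", {
  set.seed(18)
  tr <- ape::rtree(8)
  ok <- TRUE
  for (i in 1:2000) {
    prop <- chronoforge:::.spr_propose(tr)
    if (is.null(prop)) next
    p <- prop$tree
    tab <- tabulate(p$edge[, 2], nbins = 8 + p$Nnode)
    ok <- ok &&
      setequal(p$tip.label, tr$tip.label) &&
      p$Nnode == tr$Nnode &&
      !anyDuplicated(p$tip.label) &&
      all(p$edge.length >= 0) &&
      sum(tab == 1) == nrow(p$edge) &&   # exactly one parent per node
      isTRUE(tryCatch(validate_phylogram(p), error = function(e) FALSE))
    if (!ok) break
  }
  expect_true(ok)
})

test_that("strong signal recovers the true 4-taxon topology", {
  set.seed(19)
  true_tree <- parse_newick("((A:0.1,B:0.1):0.15,(C:0.1,D:0.1):0.15);")
  mod <- aa_model("poisson", ncat = 1L)
  # simulate on the true tree
  ages <- c(0, 0, 0, 0, 0.25, 0.1, 0.1)
  chrono <- chronoforge:::.tree_with_ages(true_tree, ages)
  rts <- simulate_rates(chrono, clock_model("cl", mu_r = 1))
  sim <- simulate_alignment(chrono, rts, mod, gene_lengths = 600L)
  fit <- infer_phylogeny(sim$supermatrix$matrix, mod, cycles = 400,
                         burnin = 120, chains = 2, seed = 20,
                         estimate_alpha = FALSE)
  combined <- unlist(lapply(fit$traces, function(tr) trace_retained(tr)$trees),
                     recursive = FALSE)
  cf <- clade_frequencies(combined)
  pp_ab <- cf$freq[cf$clade == "A,B"]
  pp_cd <- cf$freq[cf$clade == "C,D"]
  expect_gt(min(pp_ab, pp_cd), 0.95)
  expect_true(fit$convergence$max_diff < 0.3)
})

test_that("two-taxon posterior matches the ML grid oracle", {
  set.seed(23)
  wag <- aa_model("poisson", ncat = 1L)
  # pair at true distance 0.3
  pi <- rep(1 / 20, 20)
  pair <- simulate_pair(0.3, uniform_exchangeabilities(), pi, 3000)
  dat <- rbind(A = pair$a, B = pair$b)
  tr <- run_phylogram_chain(dat, wag, chain_config(400, thin = 1,
                                                   burnin = 100, seed = 24))
  post <- trace_retained(tr)
  # grid oracle for the total path length
  counts <- table(factor(match(pair$a, aa_states()), levels = 1:20),
                  factor(match(pair$b, aa_states()), levels = 1:20))
  Q <- build_rate_matrix(uniform_exchangeabilities(), pi)
  e <- eigen(Q); Vi <- solve(e$vectors)
  ll <- function(d) {
    P <- Re(e$vectors %*% diag(exp(e$values * d)) %*% Vi)
    sum(unclass(counts) * log(pmax(P / 20, 1e-300)))
  }
  grid <- seq(0.1, 0.6, by = 1e-3)
  d_ml <- grid[which.max(vapply(grid, ll, numeric(1)))]
  expect_lt(abs(mean(post$scalars$tree_length) - d_ml), 0.02)
})

test_that("age proposals respect node ordering and tip ages", {
  set.seed(25)
  b <- make_benchmark("tiny", seed = 5)
  tr <- run_dating_chain(b$tree, likelihood_off = TRUE,
                         clock = clock_model("ln", mu_r = 1e-3, sigma2 = 1e-3),
                         calibrations = b$calibrations,
                         config = chain_config(200, thin = 1, burnin = 20,
                                               seed = 26))
  ntip <- length(b$tree$tip.label)
  tips_zero <- all(tr$ages[, seq_len(ntip)] == 0)
  ordered <- all(apply(tr$ages, 1L, function(a) {
    all(a[b$tree$edge[, 1]] > a[b$tree$edge[, 2]])
  }))
  expect_true(tips_zero)
  expect_true(ordered)
  expect_true(all(tr$rates > 0))
})

test_that("convergence report flags agreement and disagreement", {
  tr <- parse_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  cfg <- chain_config(40, thin = 1, burnin = 5, seed = 30)
  a <- run_dating_chain(tr, likelihood_off = TRUE,
                        clock = clock_model("cl", mu_r = 1e-3), config = cfg)
  rep_same <- convergence_report(a, a)
  expect_equal(rep_same$scalar_discrepancy[["root_age"]], 0)
  expect_true(rep_same$pass)

  # deliberately unconverged: two conflicting fixed topologies, no
  # topology moves
  set.seed(31)
  dat <- matrix(sample(aa_states(), 4 * 40, replace = TRUE), 4, 40,
                dimnames = list(c("A", "B", "C", "D"), NULL))
  t1 <- parse_newick("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  t2 <- parse_newick("((A:0.1,C:0.1):0.1,(B:0.1,D:0.1):0.1);")
  cfgp <- chain_config(10, thin = 1, burnin = 2, seed = 32)
  pa <- run_phylogram_chain(dat, aa_model("poisson", ncat = 1L), cfgp,
                            start_tree = t1, sample_topology = FALSE)
  pb <- run_phylogram_chain(dat, aa_model("poisson", ncat = 1L), cfgp,
                            start_tree = t2, sample_topology = FALSE)
  rep_bad <- convergence_report(pa, pb)
  expect_equal(rep_bad$max_diff, 1)
  expect_false(rep_bad$pass)

  # duplicated phylogram traces give max_diff 0
  expect_equal(convergence_report(pa, pa)$max_diff, 0)
})
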