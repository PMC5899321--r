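# Relaxed-clock densities, birth-death age prior, calibrations, root prior.

test_that("LN clock density matches the closed-form normal oracle", {
  # two-node chain: root -> single cherry
  tr <- parse_newick("(A:10,B:10);")
  clock <- clock_model("ln", mu_r = 1e-3, sigma2 = 0.002, root_spread = 0.5)
  # one internal node (root); rates indexed 1..3 (A, B, root)
  rates <- c(1.2e-3, 0.8e-3, 1.0e-3)
  ld <- ln_clock_logdensity(rates, tr, clock)
  dt <- 10
  oracle <- dnorm(log(rates[3]), log(clock$mu_r), 0.5, log = TRUE) - log(rates[3]) +
    sum(vapply(1:2, function(v) {
      dnorm(log(rates[v]), log(rates[3]) - clock$sigma2 * dt / 2,
            sqrt(clock$sigma2 * dt), log = TRUE) - log(rates[v])
    }, numeric(1)))
  expect_equal(ld, oracle, tolerance = 1e-12)
  expect_equal(ln_clock_logdensity(c(-1, 1, 1), tr, clock), -Inf)
})

test_that("LN child-rate density integrates to one over the child rate", {
  tr <- parse_newick("(A:10,B:10);")
  clock <- clock_model("ln", mu_r = 1e-3, sigma2 = 0.005)
  base <- c(NA, 1e-3, 1.3e-3)  # child A varies; B and root fixed
  dens <- function(r) {
    vapply(r, function(x) {
      exp(ln_clock_logdensity(c(x, base[2], base[3]), tr, clock))
    }, numeric(1))
  }
  total <- integrate(dens, 0, Inf, rel.tol = 1e-8)$value
  # constant factor: root density times the fixed child B term
  dt <- 10
  fixed_part <- exp(
    dnorm(log(base[3]), log(clock$mu_r), clock$root_spread, log = TRUE) -
      log(base[3]) +
      dnorm(log(base[2]), log(base[3]) - clock$sigma2 * dt / 2,
            sqrt(clock$sigma2 * dt), log = TRUE) - log(base[2]))
  expect_equal(total / fixed_part, 1, tolerance = 1e-6)
})

test_that("strict-clock limits of LN and UGAM behave degenerately", {
  tr <- parse_newick("(A:10,B:10);")
  cl0 <- clock_model("ln", mu_r = 1e-3, sigma2 = 0)
  expect_true(is.finite(ln_clock_logdensity(rep(1e-3, 3), tr, cl0)))
  expect_equal(ln_clock_logdensity(c(1e-3, 2e-3, 1e-3), tr, cl0), -Inf)

  ug0 <- clock_model("ugam", mu_r = 1e-3, nu = 0)
  expect_equal(ugam_clock_logdensity(rep(1e-3, 5), ug0), 0)
  expect_equal(ugam_clock_logdensity(c(rep(1e-3, 4), 2e-3), ug0), -Inf)
})

test_that("UGAM density matches the hand-written gamma log-pdf", {
  clock <- clock_model("ugam", mu_r = 2e-3, nu = 0.4)
  shape <- 1 / clock$nu; scale <- clock$nu * clock$mu_r
  set.seed(61)
  r <- rgamma(50, shape, scale = scale)
  oracle <- sum((shape - 1) * log(r) - r / scale - lgamma(shape) -
                  shape * log(scale))
  expect_equal(ugam_clock_logdensity(r, clock), oracle, tolerance = 1e-12)
})

test_that("UGAM simulated branch rates have the stated mean and variance", {
  set.seed(62)
  tr <- simulate_chronogram(600, lambda = 0.05, mu = 0, root_age = 100)
  clock <- clock_model("ugam", mu_r = 2e-3, nu = 0.3)
  rts <- simulate_rates(tr, clock)
  br <- rts$branch_rates[tr$edge[, 2]]
  se <- sqrt(clock$nu * clock$mu_r^2 / length(br))
  expect_lt(abs(mean(br) - clock$mu_r), 3 * se)
})

test_that("conditioned birth-death age prior matches forward simulation (Yule)", {
  set.seed(63)
  lambda <- 0.9; T <- 1; n <- 5
  fwd <- forward_yule_ages(n, lambda, T, 600)
  # package draws via the generator (which uses the same conditional law
  # the density encodes); compare pooled non-root node ages
  gen <- unlist(lapply(1:600, function(i) {
    tr <- simulate_chronogram(n, lambda = lambda, mu = 0, root_age = T)
    ages <- node_ages(tr)
    ages[(n + 2L):(2L * n - 1L)]
  }))
  ks <- suppressWarnings(ks.test(fwd, gen))
  expect_gt(ks$p.value, 0.01)
})

test_that("birth-death log density handles degenerate and invalid input", {
  tr <- parse_newick("(A:5,B:5);")
  ages <- c(0, 0, 5)
  expect_equal(birthdeath_ages_logdensity(tr, ages, 0.1, 0.02), 0)
  tr4 <- parse_newick("((A:2,B:2):3,(C:4,D:4):1);")
  ages4 <- c(0, 0, 0, 0, 5, 2, 4)
  expect_true(is.finite(birthdeath_ages_logdensity(tr4, ages4, 0.1, 0.02)))
  # parent younger than child
  bad <- c(0, 0, 0, 0, 3, 2, 4)
  expect_equal(birthdeath_ages_logdensity(tr4, bad, 0.1, 0.02), -Inf)
  # nonzero tip age (not ultrametric in time)
  bad2 <- c(1, 0, 0, 0, 5, 2, 4)
  expect_equal(birthdeath_ages_logdensity(tr4, bad2, 0.1, 0.02), -Inf)
  # density integrates to 1 over one node age given the others
  dens <- function(x) {
    vapply(x, function(v) {
      exp(birthdeath_ages_logdensity(tr4, c(0, 0, 0, 0, 5, v, 4), 0.1, 0.02) -
            birthdeath_ages_logdensity(tr4, c(0, 0, 0, 0, 5, 2, 4), 0.1, 0.02) +
            chronoforge:::.bd_logdens(2, 0.1, 0.02, 5))
    }, numeric(1))
  }
  expect_equal(integrate(dens, 0, 5, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-6)
})

test_that("soft calibrations have flat plateaus and the stated tail masses", {
  cal <- calibration("Chordata", c("Homo_sapiens", "Oikopleura_dioica"),
                     min_age = 519, max_age = 581, eps = 0.025)
  # plateau: identical log factor everywhere inside the bounds
  inside <- calibration_logfactor(seq(519, 581, length.out = 50), cal)
  expect_true(all(inside == 0))
  # mass within bounds = 1 - 2 eps by numeric integration
  f <- function(x) exp(calibration_logfactor(x, cal))
  plateau <- integrate(f, 519, 581)$value
  below <- integrate(f, -2000, 519)$value
  above <- integrate(f, 581, 3000)$value
  expect_equal(plateau / (plateau + below + above), 1 - 2 * cal$eps,
               tolerance = 1e-4)
  # far outside: strongly penalized
  expect_lt(calibration_logfactor(519 - 10 * cal$tail_scale, cal), -5)

  # one-sided minimum: lower tail carries eps relative to the reference
  # plateau width (the bound's own age)
  cal1 <- calibration("Echinoidea", "Strongylocentrotus_purpuratus",
                      min_age = 255, eps = 0.025)
  tail_mass <- integrate(function(x) exp(calibration_logfactor(x, cal1)),
                         -5000, 255)$value
  expect_equal(tail_mass / (tail_mass + cal1$width), cal1$eps,
               tolerance = 1e-4)
  expect_error(calibration("bad", "A", min_age = 10, max_age = 5), "min_age")
})

test_that("the packaged 13-calibration fixture loads and attaches to the scaffold", {
  cals <- read_calibrations()
  expect_length(cals, 13L)
  expect_equal(cals[[1]]$clade, "Chordata")
  expect_equal(cals[[1]]$min_age, 519)
  expect_equal(cals[[1]]$max_age, 581)
  expect_true(is.na(cals[[13]]$max_age))
  expect_equal(cals[[13]]$min_age, 255)
  set.seed(64)
  tr <- deutero63_chronogram()
  expect_length(tr$tip.label, 63L)
  nodes <- chronoforge:::.attach_calibrations(tr, cals)
  ages <- node_ages(tr)
  for (i in seq_along(cals)) {
    age <- ages[nodes[i]]
    if (!is.na(cals[[i]]$min_age)) expect_gte(age, cals[[i]]$min_age)
    if (!is.na(cals[[i]]$max_age)) expect_lte(age, cals[[i]]$max_age)
  }
  # distinct constraints hit distinct nodes except the deliberately shared
  # Chordata/Olfactores-style nesting
  expect_gte(length(unique(nodes)), 12L)
})

test_that("root prior density and quantiles follow the exponential form", {
  rp <- root_prior(540)
  expect_equal(root_prior_logdensity(0, rp), -log(540))
  expect_equal(root_prior_logdensity(-1, rp), -Inf)
  expect_equal(qexp(0.5, 1 / 540), 540 * log(2), tolerance = 1e-9)
  set.seed(65)
  x <- rexp(1e6, 1 / 540)
  expect_lt(abs(mean(x) - 540), 3 * 540 / sqrt(1e6))
})
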