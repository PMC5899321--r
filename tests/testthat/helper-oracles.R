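# Independent oracles and small fixture builders used across the suite.

# Brute-force pruning likelihood by exhaustive summation over all internal
# node states, per site and gamma category. Independent of the engine:
# builds P matrices directly from matrix exponentials via eigen().
brute_force_loglik <- function(tree, data, model) {
  states <- aa_states()
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  g <- discrete_gamma_rates(model$alpha, model$ncat)
  data <- data[tree$tip.label, , drop = FALSE]
  nsites <- ncol(data)
  comp_of <- if (model$is_cat) {
    sc <- model$site_comp
    if (is.null(sc)) rep(1L, nsites) else sc
  } else rep(1L, nsites)
  profs <- if (model$is_cat) model$profiles else list(model$freqs)
  eigs <- lapply(profs, function(p) {
    p <- p / sum(p)
    list(eig = eigen(build_rate_matrix(model$rho, p)), pi = p)
  })
  pmat <- function(ei, t) {
    e <- eigs[[ei]]$eig
    P <- e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors)
    Re(P)
  }
  internals <- (ntip + 1L):nnode
  m <- length(internals)
  grid <- as.matrix(expand.grid(rep(list(1:20), m)))
  sapply(seq_len(nsites), function(s) {
    ci <- comp_of[s]
    pi <- eigs[[ci]]$pi
    tip_idx <- match(data[, s], states)
    tot <- 0
    for (k in seq_len(model$ncat)) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
        pmat(ci, tree$edge.length[e] * g$rates[k])
      })
      lik <- pi[grid[, 1L]]   # root = first internal (ape: ntip + 1)
      for (e in seq_len(nrow(tree$edge))) {
        pa <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        astate <- grid[, match(pa, internals)]
        if (ch <= ntip) {
          b <- tip_idx[ch]
          lik <- lik * (if (is.na(b)) 1 else Ps[[e]][cbind(astate, b)])
        } else {
          bstate <- grid[, match(ch, internals)]
          lik <- lik * Ps[[e]][cbind(astate, bstate)]
        }
      }
      tot <- tot + g$weights[k] * sum(lik)
    }
    log(tot)
  })
}

# Forward-simulated Yule process conditioned (by rejection) on n tips at
# time T; returns the pooled internal node ages (excluding the root).
forward_yule_ages <- function(n, lambda, T, nsim) {
  out <- numeric(0)
  while (nsim > 0L) {
    t <- 0; k <- 2L; births <- numeric(0)
    repeat {
      t <- t + rexp(1, k * lambda)
      if (t >= T) break
      births <- c(births, t)
      k <- k + 1L
    }
    if (k == n) {
      out <- c(out, T - births)  # ages before present
      nsim <- nsim - 1L
    }
  }
  out
}

# Simulate an aligned sequence pair at a given true distance under a
# reversible model (used by the ML-distance tests).
simulate_pair <- function(d, rho, pi, nsites) {
  Q <- build_rate_matrix(rho, pi)
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * d)) %*% solve(e$vectors))
  P <- pmax(P, 0); P <- P / rowSums(P)
  a <- sample.int(20L, nsites, replace = TRUE, prob = pi)
  b <- vapply(a, function(x) sample.int(20L, 1L, prob = P[x, ]), integer(1))
  list(a = aa_states()[a], b = aa_states()[b])
}

# small helper: random gene alignment with given taxa
random_gene <- function(id, taxa, nsites) {
  seqs <- vapply(taxa, function(tx) {
    paste(sample(aa_states(), nsites, replace = TRUE), collapse = "")
  }, character(1))
  gene_alignment(id, seqs)
}

# trivial chronogram-mode trace with given age samples for one node set
fake_dating_trace <- function(tree, ages_matrix, rates_matrix = NULL,
                              clock = clock_model("cl", mu_r = 1e-3)) {
  n <- nrow(ages_matrix)
  if (is.null(rates_matrix)) {
    rates_matrix <- matrix(clock$mu_r, n, ncol(ages_matrix))
  }
  scal <- data.frame(cycle = seq_len(n), lnL = 0, lnPrior = 0,
                     root_age = ages_matrix[, length(tree$tip.label) + 1L],
                     mu_r = clock$mu_r, clock_var = 0, lambda = 0.1,
                     mu_death = 0.05)
  posterior_trace("chronogram", scal, ages = ages_matrix,
                  rates = rates_matrix, tree = tree,
                  config = chain_config(n, thin = 1, burnin = 0, seed = 1),
                  clock = clock)
}
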