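# Metropolis-within-Gibbs sampler for topology + branch lengths under the
# substitution models (phylogram mode). Branch lengths carry an
# exponential prior; alpha a log-uniform prior; GTR frequencies and
# exchangeabilities flat Dirichlet priors.

.BL_PRIOR_RATE <- 10      # exponential prior on branch lengths, mean 0.1
.ALPHA_RANGE <- c(0.01, 100)

# ---- topology proposals ----------------------------------------------

# Rooted NNI: pick an internal edge (p -> v, v internal, p has another
# child s), swap s with one of v's children. Uniform over (edge, swap)
# pairs; symmetric.
.nni_propose <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  cand <- which(tree$edge[, 2L] > ntip)  # edges to internal nodes
  if (!length(cand)) return(NULL)
  e <- cand[sample.int(length(cand), 1L)]
  p <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
  sib_rows <- which(tree$edge[, 1L] == p & tree$edge[, 2L] != v)
  child_rows <- which(tree$edge[, 1L] == v)
  s_row <- sib_rows[sample.int(length(sib_rows), 1L)]
  s <- tree$edge[s_row, 2L]
  if (p == root && length(sib_rows) == 1L && s > ntip) {
    # a 2-child root: swapping with the whole sibling subtree only
    # re-roots; swap across the root into the sibling's children instead
    s_rows2 <- which(tree$edge[, 1L] == s)
    s_row <- s_rows2[sample.int(length(s_rows2), 1L)]
    s <- tree$edge[s_row, 2L]
  }
  c_row <- child_rows[sample.int(length(child_rows), 1L)]
  cc <- tree$edge[c_row, 2L]
  tree$edge[s_row, 2L] <- cc
  tree$edge[c_row, 2L] <- s
  # each node keeps its own branch length
  tmp <- tree$edge.length[s_row]
  tree$edge.length[s_row] <- tree$edge.length[c_row]
  tree$edge.length[c_row] <- tmp
  list(tree = ape::reorder.phylo(tree, "cladewise"), log_hastings = 0)
}

# Subtree prune and regraft with uniform insertion-point; Hastings ratio
# log(target length / reattachment-edge length created by the reverse).
.spr_propose <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  # prune candidates: nodes whose parent is not the root (so the parent
  # can be collapsed) — and the parent must have exactly 2 children
  deg <- tabulate(tree$edge[, 1L], nbins = nnode)
  cand <- which(seq_len(nnode) != root & parent != root & parent != 0L &
                  deg[pmax(parent, 1L)] == 2L)
  if (!length(cand)) return(NULL)
  v <- cand[sample.int(length(cand), 1L)]
  p <- parent[v]; g <- parent[p]
  s <- tree$edge[tree$edge[, 1L] == p & tree$edge[, 2L] != v, 2L][1L]
  # subtree tip set of v (to exclude as targets)
  in_sub <- logical(nnode); in_sub[v] <- TRUE
  ord <- .preorder_nodes(tree)
  for (w in ord) if (!in_sub[w] && w != root && in_sub[parent[w]]) in_sub[w] <- TRUE
  row_pv <- which(tree$edge[, 2L] == v)
  row_ps <- which(tree$edge[, 2L] == s)
  row_gp <- which(tree$edge[, 2L] == p)
  len_rev <- tree$edge.length[row_ps] + tree$edge.length[row_gp]
  # collapse p: g -> s
  edge <- tree$edge; elen <- tree$edge.length
  edge[row_ps, 1L] <- g
  elen[row_ps] <- len_rev
  drop <- row_gp
  # target edges: any edge not inside the subtree, not edge to v, not the
  # merged edge's duplicates
  valid <- which(!in_sub[edge[, 2L]] & seq_len(nrow(edge)) != row_pv &
                   seq_len(nrow(edge)) != drop)
  if (!length(valid)) return(NULL)
  t_row <- valid[sample.int(length(valid), 1L)]
  a <- edge[t_row, 1L]; b <- edge[t_row, 2L]
  len_t <- elen[t_row]
  u <- runif(1)
  # reuse p as the new attachment node on edge a -> b
  edge[t_row, ] <- c(a, p); elen[t_row] <- u * len_t
  edge[drop, ] <- c(p, b); elen[drop] <- (1 - u) * len_t
  tree$edge <- edge; tree$edge.length <- elen
  list(tree = ape::reorder.phylo(tree, "cladewise"),
       log_hastings = log(len_t) - log(len_rev))
}

# ---- prior ------------------------------------------------------------

.phylogram_logprior <- function(elens, model) {
  lp <- sum(dexp(elens, rate = .BL_PRIOR_RATE, log = TRUE))
  if (model$alpha < .ALPHA_RANGE[1L] || model$alpha > .ALPHA_RANGE[2L]) {
    return(-Inf)
  }
  lp - log(model$alpha)   # log-uniform on alpha
}

# ---- driver -----------------------------------------------------------

#' Run a phylogram-mode MCMC chain
#'
#' Samples topology (optional), branch lengths, gamma shape, and for GTR /
#' CAT models their frequency parameters, under the exponential
#' branch-length prior. One cycle sweeps every branch, then the scheduled
#' topology, CAT, and hyperparameter moves.
#'
#' @param data Character matrix (taxa x sites) or [concatenate()] result.
#' @param model An [aa_model()]; `alpha` is the starting value when
#'   `estimate_alpha = TRUE`.
#' @param config A [chain_config()].
#' @param start_tree Optional starting `"phylo"`; default random.
#' @param sample_topology Enable NNI/SPR moves (default `TRUE`).
#' @param estimate_alpha Sample the gamma shape (default `TRUE` when
#'   `ncat > 1`).
#' @param chain_id Offsets the seed for multi-chain runs.
#' @return A `"cf_trace"` (mode `"phylogram"`) with sampled trees.
#' @export
run_phylogram_chain <- function(data, model, config, start_tree = NULL,
                                sample_topology = TRUE,
                                estimate_alpha = model$ncat > 1L,
                                chain_id = 1L) {
  if (inherits(data, "cf_supermatrix")) data <- data$matrix
  taxa <- rownames(data)
  set.seed(config$seed + 1000L * (chain_id - 1L))
  tree <- if (is.null(start_tree)) {
    tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
    tr$edge.length <- rexp(nrow(tr$edge), rate = .BL_PRIOR_RATE)
    tr
  } else start_tree
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rexp(nrow(tree$edge), rate = .BL_PRIOR_RATE)
  }
  is_gtr <- model$name %in% c("gtr", "cat-gtr")
  is_cat <- model$is_cat
  nsites <- ncol(data)
  cat_state <- NULL
  if (is_cat) {
    cat_state <- cat_state_init(nsites, n_init = length(model$profiles))
    cat_state$profiles <- model$profiles
    if (!is.null(model$site_comp)) cat_state$site_comp <- model$site_comp
    model$profiles <- cat_state$profiles
    model$site_comp <- cat_state$site_comp
  }
  eng <- .make_engine(tree, data, model)
  lnL <- engine_loglik(eng$ptr)
  engine_commit(eng$ptr)
  retry <- 0L
  while (!is.finite(lnL) && retry < 20L) {
    tree$edge.length <- rexp(nrow(tree$edge), rate = .BL_PRIOR_RATE)
    eng <- .make_engine(tree, data, model)
    lnL <- engine_loglik(eng$ptr)
    engine_commit(eng$ptr)
    retry <- retry + 1L
  }
  if (!is.finite(lnL)) stop("could not find a starting state with finite posterior")
  moves <- config$moves
  w_topo <- if (!is.null(moves) && "topology" %in% names(moves)) moves[["topology"]] else 2L
  w_cat <- if (!is.null(moves) && "cat" %in% names(moves)) moves[["cat"]] else 1L
  n_rec <- floor(config$cycles / config$thin)
  scal <- data.frame(cycle = integer(n_rec), lnL = numeric(n_rec),
                     lnPrior = numeric(n_rec), alpha = numeric(n_rec),
                     tree_length = numeric(n_rec),
                     n_comp = integer(n_rec))
  trees <- vector("list", n_rec)
  models <- vector("list", n_rec)
  rec <- 0L
  for (cyc in seq_len(config$cycles)) {
    lp <- .phylogram_logprior(tree$edge.length, model)
    # branch-length sweep (multiplier proposals)
    for (ei in seq_len(nrow(tree$edge))) {
      cur <- tree$edge.length[ei]
      m <- exp(runif(1, -0.5, 0.5))
      newl <- cur * m
      node <- tree$edge[ei, 2L]
      engine_set_lengths(eng$ptr, node, newl)
      lnL_new <- engine_loglik(eng$ptr)
      dprior <- dexp(newl, .BL_PRIOR_RATE, log = TRUE) -
        dexp(cur, .BL_PRIOR_RATE, log = TRUE)
      if (.mh_accept(lnL_new - lnL + dprior + log(m))) {
        engine_commit(eng$ptr)
        tree$edge.length[ei] <- newl
        lnL <- lnL_new
      } else {
        engine_revert(eng$ptr)
      }
    }
    # topology moves
    if (sample_topology && length(taxa) >= 4L) {
      for (k in seq_len(w_topo)) {
        prop <- if (runif(1) < 0.7) .nni_propose(tree) else .spr_propose(tree)
        if (is.null(prop)) next
        eng_new <- .make_engine(prop$tree, data, model)
        lnL_new <- engine_loglik(eng_new$ptr)
        engine_commit(eng_new$ptr)
        if (.mh_accept(lnL_new - lnL + prop$log_hastings)) {
          tree <- prop$tree
          eng <- eng_new
          lnL <- lnL_new
        }
      }
    }
    # CAT sweeps
    if (is_cat && w_cat > 0L) {
      cat_state <- cat_gibbs_sweep(cat_state, tree, data, rho = model$rho,
                                   alpha = model$alpha, ncat = model$ncat)
      cat_state <- sample_component_profiles(cat_state, tree, data,
                                             rho = model$rho,
                                             alpha = model$alpha,
                                             ncat = model$ncat)
      cat_state <- .cat_update_conc(cat_state)
      model$profiles <- cat_state$profiles
      model$site_comp <- cat_state$site_comp
      eng <- .engine_update_model(eng, model)
      lnL <- engine_loglik(eng$ptr)
      engine_commit(eng$ptr)
    }
    # hyperparameters
    if (estimate_alpha && model$ncat > 1L) {
      prop_a <- model$alpha * exp(runif(1, -0.3, 0.3))
      if (prop_a >= .ALPHA_RANGE[1L] && prop_a <= .ALPHA_RANGE[2L]) {
        mod_new <- model; mod_new$alpha <- prop_a
        eng <- .engine_update_model(eng, mod_new)
        lnL_new <- engine_loglik(eng$ptr)
        engine_commit(eng$ptr)
        # log-uniform prior: density 1/alpha; log-scale RW is symmetric
        # in log(alpha), so prior and Hastings terms cancel
        if (.mh_accept(lnL_new - lnL)) {
          model <- mod_new
          lnL <- lnL_new
        } else {
          eng <- .engine_update_model(eng, model)
          lnL <- engine_loglik(eng$ptr)
          engine_commit(eng$ptr)
        }
      }
    }
    if (is_gtr) {
      # frequency move (flat Dirichlet prior)
      if (!is_cat) {
        kap <- 500
        prop_f <- .rdirichlet(kap * model$freqs + 0.05)
        hast <- .ddirichlet_log(model$freqs, kap * prop_f + 0.05) -
          .ddirichlet_log(prop_f, kap * model$freqs + 0.05)
        mod_new <- model; mod_new$freqs <- prop_f
        eng <- .engine_update_model(eng, mod_new)
        lnL_new <- engine_loglik(eng$ptr)
        engine_commit(eng$ptr)
        if (.mh_accept(lnL_new - lnL + hast)) {
          model <- mod_new; lnL <- lnL_new
        } else {
          eng <- .engine_update_model(eng, model)
          lnL <- engine_loglik(eng$ptr)
          engine_commit(eng$ptr)
        }
      }
      # exchangeability move on the normalized lower triangle
      lower <- lower.tri(model$rho)
      rv <- model$rho[lower]; rv <- rv / sum(rv)
      kap <- 2000
      prop_r <- .rdirichlet(kap * rv + 0.02)
      hast <- .ddirichlet_log(rv, kap * prop_r + 0.02) -
        .ddirichlet_log(prop_r, kap * rv + 0.02)
      rho_new <- model$rho
      rho_new[lower] <- prop_r * sum(model$rho[lower])
      rho_new[upper.tri(rho_new)] <- t(rho_new)[upper.tri(rho_new)]
      mod_new <- model; mod_new$rho <- rho_new
      eng <- .engine_update_model(eng, mod_new)
      lnL_new <- engine_loglik(eng$ptr)
      engine_commit(eng$ptr)
      if (.mh_accept(lnL_new - lnL + hast)) {
        model <- mod_new; lnL <- lnL_new
      } else {
        eng <- .engine_update_model(eng, model)
        lnL <- engine_loglik(eng$ptr)
        engine_commit(eng$ptr)
      }
    }
    # periodic numerical guard: rebuild the engine from scratch
    if (cyc %% 1000L == 0L) {
      fresh <- engine_loglik(.make_engine(tree, data, model)$ptr)
      if (abs(fresh - lnL) > 1e-6 * max(1, abs(fresh))) {
        warning("incremental likelihood drift detected; resynchronized")
      }
      lnL <- fresh
    }
    if (cyc %% config$thin == 0L) {
      rec <- rec + 1L
      scal$cycle[rec] <- cyc
      scal$lnL[rec] <- lnL
      scal$lnPrior[rec] <- .phylogram_logprior(tree$edge.length, model)
      scal$alpha[rec] <- model$alpha
      scal$tree_length[rec] <- sum(tree$edge.length)
      scal$n_comp[rec] <- if (is_cat) length(cat_state$profiles) else 1L
      trees[[rec]] <- tree
      models[[rec]] <- model
    }
  }
  posterior_trace("phylogram", scal, trees = trees, config = config,
                  model = model, models = models)
}
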