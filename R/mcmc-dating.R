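# Fixed-topology divergence-time MCMC: node ages and lineage rates under
# a relaxed (LN/UGAM) or strict clock, birth-death age prior, soft fossil
# calibrations, and exponential root prior.

.MU_R_RANGE <- c(1e-8, 1e2)
.LAMBDA_PRIOR_MEAN <- 0.1    # birth rate hyperprior (per lineage per Mya)
.MU_PRIOR_MEAN <- 0.05       # death rate hyperprior

# effective per-edge substitution branch lengths given ages + rates
.dating_branch_lengths <- function(topo, ages, state, clock) {
  p <- topo$edge[, 1L]; v <- topo$edge[, 2L]
  dur <- ages[p] - ages[v]
  eff <- switch(clock$kind,
    cl = rep(clock$mu_r, length(dur)),
    ln = (state$rates[p] + state$rates[v]) / 2,
    ugam = state$branch_rates[v])
  dur * eff
}

.dating_logprior <- function(topo, ages, state, clock, calibrations,
                             cal_nodes, rprior) {
  root <- length(topo$tip.label) + 1L
  lp <- root_prior_logdensity(ages[root], rprior)
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + birthdeath_ages_logdensity(topo, ages, state$lambda, state$mu_d)
  if (!is.finite(lp)) return(-Inf)
  if (length(cal_nodes)) {
    for (i in seq_along(cal_nodes)) {
      lp <- lp + calibration_logfactor(ages[cal_nodes[i]], calibrations[[i]])
    }
  }
  lp <- lp + switch(clock$kind,
    cl = 0,
    ln = ln_clock_logdensity(state$rates, topo, clock, ages = ages),
    ugam = ugam_clock_logdensity(state$branch_rates[topo$edge[, 2L]], clock))
  if (!is.finite(lp)) return(-Inf)
  # hyperpriors
  lp <- lp + dexp(state$lambda, 1 / .LAMBDA_PRIOR_MEAN, log = TRUE) +
    dexp(state$mu_d, 1 / .MU_PRIOR_MEAN, log = TRUE)
  if (clock$mu_r < .MU_R_RANGE[1L] || clock$mu_r > .MU_R_RANGE[2L]) return(-Inf)
  lp <- lp - log(clock$mu_r)
  if (clock$kind == "ln") lp <- lp + dexp(clock$sigma2, 1, log = TRUE)
  if (clock$kind == "ugam") lp <- lp + dexp(clock$nu, 1, log = TRUE)
  lp
}

# initial ages: i.i.d. conditioned birth-death draws given a root age
.init_ages <- function(topo, root_age, lambda, mu_d) {
  ntip <- length(topo$tip.label)
  root <- ntip + 1L
  nnode <- ntip + topo$Nnode
  ages <- numeric(nnode)
  ages[root] <- root_age
  for (v in .preorder_nodes(topo)) {
    if (v <= ntip || v == root) next
    p <- topo$edge[topo$edge[, 2L] == v, 1L]
    # place uniformly below the parent (stays within (0, parent))
    ages[v] <- ages[p] * runif(1, 0.3, 0.9)
  }
  ages
}

#' Run a dating-mode MCMC chain (fixed topology)
#'
#' Samples internal node ages (Mya), lineage rates under the chosen clock
#' model, and the clock / diversification hyperparameters, against the
#' birth-death node-age prior, soft calibrations, exponential root prior,
#' and (unless `likelihood_off`) the pruning likelihood of the alignment.
#'
#' @param tree Rooted topology (`"phylo"`); branch lengths ignored.
#' @param data Character matrix (taxa x sites); ignored when
#'   `likelihood_off = TRUE`.
#' @param model An [aa_model()] with fixed parameters.
#' @param clock A [clock_model()]; its `mu_r`, `sigma2`/`nu` are starting
#'   values and are sampled.
#' @param calibrations List of [calibration()] objects (may be empty).
#' @param rprior A [root_prior()].
#' @param config A [chain_config()].
#' @param likelihood_off Prior-only run (sampler-correctness checks).
#' @param fix_root_age Optional fixed root age (disables the root move and
#'   the root prior term's influence).
#' @param fix_diversification Optional `list(lambda, mu)` fixing the
#'   birth-death rates (disables their moves and hyperprior sampling).
#' @param chain_id Seed offset for multi-chain runs.
#' @return A `"cf_trace"` (mode `"chronogram"`) with `ages` and `rates`
#'   sample matrices.
#' @export
run_dating_chain <- function(tree, data = NULL, model = NULL,
                             clock = clock_model("ln"),
                             calibrations = list(),
                             rprior = root_prior(540),
                             config = chain_config(1000),
                             likelihood_off = FALSE,
                             fix_root_age = NULL,
                             fix_diversification = NULL,
                             chain_id = 1L) {
  set.seed(config$seed + 1000L * (chain_id - 1L))
  topo <- tree
  ntip <- length(topo$tip.label)
  root <- ntip + 1L
  nnode <- ntip + topo$Nnode
  internal <- setdiff((ntip + 1L):nnode, root)
  cal_nodes <- if (length(calibrations)) .attach_calibrations(topo, calibrations)
               else integer(0)
  state <- if (is.null(fix_diversification)) {
    list(lambda = .LAMBDA_PRIOR_MEAN, mu_d = .MU_PRIOR_MEAN / 2)
  } else {
    list(lambda = fix_diversification$lambda, mu_d = fix_diversification$mu)
  }
  # starting state with finite prior (soft calibrations keep this easy)
  ages <- NULL
  for (try in seq_len(100L)) {
    root_age <- if (!is.null(fix_root_age)) fix_root_age else rexp(1, 1 / rprior$mean)
    ages_try <- .init_ages(topo, root_age, state$lambda, state$mu_d)
    state$rates <- rep(clock$mu_r, nnode)
    state$branch_rates <- rep(clock$mu_r, nnode)
    lp <- .dating_logprior(topo, ages_try, state, clock, calibrations,
                           cal_nodes, rprior)
    if (is.finite(lp)) { ages <- ages_try; break }
  }
  if (is.null(ages)) stop("could not initialize a finite-prior state")
  use_lik <- !likelihood_off
  eng <- NULL
  lnL <- 0
  bl_all <- function() .dating_branch_lengths(topo, ages, state, clock)
  if (use_lik) {
    ltree <- topo
    ltree$edge.length <- pmax(bl_all(), 0)
    eng <- .make_engine(ltree, data, model)
    lnL <- engine_loglik(eng$ptr)
    engine_commit(eng$ptr)
    if (!is.finite(lnL)) stop("starting state has -Inf likelihood")
  }
  lp <- .dating_logprior(topo, ages, state, clock, calibrations, cal_nodes,
                         rprior)
  children_of <- split(topo$edge[, 2L], topo$edge[, 1L])
  parent_of <- integer(nnode); parent_of[topo$edge[, 2L]] <- topo$edge[, 1L]
  # nodes whose branch length (edge above) changes when node v moves or
  # its rate changes: v itself and its children
  touched <- function(v) {
    ch <- children_of[[as.character(v)]]
    if (v == root) ch else c(v, ch)
  }
  push_lengths <- function(nodes) {
    bl <- bl_all()
    ed <- match(nodes, topo$edge[, 2L])
    engine_set_lengths(eng$ptr, nodes, pmax(bl[ed], 0))
  }
  propose <- function(newages, newstate, newclock, nodes, hastings = 0) {
    lp_new <- .dating_logprior(topo, newages, newstate, newclock,
                               calibrations, cal_nodes, rprior)
    if (!is.finite(lp_new)) return(FALSE)
    if (use_lik && length(nodes)) {
      old_ages <- ages; old_state <- state; old_clock <- clock
      ages <<- newages; state <<- newstate; clock <<- newclock
      push_lengths(nodes)
      lnL_new <- engine_loglik(eng$ptr)
      if (.mh_accept(lnL_new - lnL + lp_new - lp + hastings)) {
        engine_commit(eng$ptr)
        lp <<- lp_new; lnL <<- lnL_new
        return(TRUE)
      }
      ages <<- old_ages; state <<- old_state; clock <<- old_clock
      engine_revert(eng$ptr)
      return(FALSE)
    }
    if (.mh_accept(lp_new - lp + hastings)) {
      ages <<- newages; state <<- newstate; clock <<- newclock
      lp <<- lp_new
      return(TRUE)
    }
    FALSE
  }
  n_rec <- floor(config$cycles / config$thin)
  scal <- data.frame(cycle = integer(n_rec), lnL = numeric(n_rec),
                     lnPrior = numeric(n_rec), root_age = numeric(n_rec),
                     mu_r = numeric(n_rec), clock_var = numeric(n_rec),
                     lambda = numeric(n_rec), mu_death = numeric(n_rec))
  ages_rec <- matrix(NA_real_, n_rec, nnode)
  rates_rec <- matrix(NA_real_, n_rec, nnode)
  rec <- 0L
  for (cyc in seq_len(config$cycles)) {
    # node-age moves: alternate a uniform window slide (global,
    # independence) with a gap multiplier (local, good mixing when the
    # conditional concentrates near one end of the window)
    for (v in internal) {
      ch <- children_of[[as.character(v)]]
      lo <- max(ages[ch]); hi <- ages[parent_of[v]]
      if (hi <= lo) next
      na <- ages
      if (runif(1) < 0.5) {
        na[v] <- runif(1, lo, hi)
        hast <- 0
      } else {
        m <- exp(runif(1, -0.7, 0.7))
        na[v] <- lo + (ages[v] - lo) * m
        if (na[v] >= hi) next
        hast <- log(m)
      }
      propose(na, state, clock, touched(v), hastings = hast)
    }
    # root move (gap multiplier above oldest child)
    if (is.null(fix_root_age)) {
      ch <- children_of[[as.character(root)]]
      gap <- ages[root] - max(ages[ch])
      m <- exp(runif(1, -0.3, 0.3))
      na <- ages; na[root] <- max(ages[ch]) + gap * m
      propose(na, state, clock, touched(root), hastings = log(m))
    }
    # whole-tree age scaling
    if (is.null(fix_root_age)) {
      m <- exp(runif(1, -0.15, 0.15))
      na <- ages; na[c(root, internal)] <- ages[c(root, internal)] * m
      propose(na, state, clock, topo$edge[, 2L],
              hastings = (length(internal) + 1L) * log(m))
    }
    # joint time-rate rescaling: ages x m, rates x 1/m leaves every
    # branch substitution length (hence the likelihood) unchanged and
    # moves the chain along the rate-time ridge
    if (is.null(fix_root_age)) {
      for (k in 1:5) {  # cheap (no likelihood evaluation); repeat for mixing
        m <- exp(runif(1, -0.25, 0.25))
        na <- ages; na[c(root, internal)] <- ages[c(root, internal)] * m
        ns <- state; nc <- clock
        nc$mu_r <- clock$mu_r / m
        hast <- (length(internal) + 1L) * log(m) - log(m)
        if (clock$kind == "ln") {
          ns$rates <- state$rates / m
          hast <- hast - nnode * log(m)
        } else if (clock$kind == "ugam") {
          ns$branch_rates <- state$branch_rates / m
          hast <- hast - length(topo$edge[, 2L]) * log(m)
        }
        propose(na, ns, nc, integer(0), hastings = hast)
      }
    }
    # rate moves
    if (clock$kind == "ln") {
      for (v in seq_len(nnode)) {
        m <- exp(runif(1, -0.4, 0.4))
        ns <- state; ns$rates[v] <- state$rates[v] * m
        propose(ages, ns, clock, intersect(touched(v), topo$edge[, 2L]),
                hastings = log(m))
      }
    } else if (clock$kind == "ugam") {
      for (v in topo$edge[, 2L]) {
        m <- exp(runif(1, -0.4, 0.4))
        ns <- state; ns$branch_rates[v] <- state$branch_rates[v] * m
        propose(ages, ns, clock, v, hastings = log(m))
      }
    }
    # global rate scale
    m <- exp(runif(1, -0.2, 0.2))
    nc <- clock; nc$mu_r <- clock$mu_r * m
    ns <- state
    hast <- log(m)
    nodes <- integer(0)
    if (clock$kind == "cl") {
      nodes <- topo$edge[, 2L]
    } else if (clock$kind == "ln") {
      # scale all node rates jointly with mu_r for better mixing
      ns$rates <- state$rates * m
      hast <- hast + nnode * log(m)
      nodes <- topo$edge[, 2L]
    } else {
      ns$branch_rates <- state$branch_rates * m
      hast <- hast + length(topo$edge[, 2L]) * log(m)
      nodes <- topo$edge[, 2L]
    }
    propose(ages, ns, nc, nodes, hastings = hast)
    # clock variance
    if (clock$kind %in% c("ln", "ugam")) {
      m <- exp(runif(1, -0.4, 0.4))
      nc <- clock
      if (clock$kind == "ln") nc$sigma2 <- clock$sigma2 * m
      else nc$nu <- clock$nu * m
      propose(ages, state, nc, integer(0), hastings = log(m))
    }
    # diversification hyperparameters (prior only)
    if (is.null(fix_diversification)) for (par in c("lambda", "mu_d")) {
      m <- exp(runif(1, -0.4, 0.4))
      ns <- state; ns[[par]] <- state[[par]] * m
      if (ns$lambda > ns$mu_d) {
        propose(ages, ns, clock, integer(0), hastings = log(m))
      }
    }
    if (use_lik && cyc %% 1000L == 0L) {
      ltree <- topo; ltree$edge.length <- pmax(bl_all(), 0)
      fresh <- engine_loglik(.make_engine(ltree, data, model)$ptr)
      if (abs(fresh - lnL) > 1e-6 * max(1, abs(fresh))) {
        warning("incremental likelihood drift detected; resynchronized")
      }
      lnL <- fresh
    }
    if (cyc %% config$thin == 0L) {
      rec <- rec + 1L
      scal$cycle[rec] <- cyc
      scal$lnL[rec] <- lnL
      scal$lnPrior[rec] <- lp
      scal$root_age[rec] <- ages[root]
      scal$mu_r[rec] <- clock$mu_r
      scal$clock_var[rec] <- switch(clock$kind, ln = clock$sigma2,
                                    ugam = clock$nu, cl = 0)
      scal$lambda[rec] <- state$lambda
      scal$mu_death[rec] <- state$mu_d
      ages_rec[rec, ] <- ages
      rates_rec[rec, ] <- switch(clock$kind,
                                 ln = state$rates,
                                 ugam = state$branch_rates,
                                 cl = rep(clock$mu_r, nnode))
    }
  }
  posterior_trace("chronogram", scal, ages = ages_rec, rates = rates_rec,
                  tree = topo, config = config, model = model, clock = clock)
}

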