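# CAT-style Dirichlet-process profile mixture: Gibbs allocation sweeps
# (auxiliary-component flavour) and Metropolis updates of component
# profiles and of the DP concentration.

#' Initialize a CAT mixture state
#'
#' @param nsites Number of alignment sites.
#' @param n_init Initial number of components (sites allocated at random).
#' @param conc Dirichlet-process concentration.
#' @param base_alpha Symmetric Dirichlet base-measure parameter over
#'   profiles (default 1).
#' @return Object of class `"cf_cat_state"`: `profiles` (list of
#'   frequency vectors), `site_comp` (1-based allocation), `conc`,
#'   `base_alpha`.
#' @export
cat_state_init <- function(nsites, n_init = 1L, conc = 1, base_alpha = 1) {
  profiles <- lapply(seq_len(n_init), function(i) .rdirichlet(rep(base_alpha, 20)))
  structure(list(profiles = profiles,
                 site_comp = sample.int(n_init, nsites, replace = TRUE),
                 conc = conc, base_alpha = base_alpha),
            class = "cf_cat_state")
}

# per-site log-likelihood vector under a single profile (all sites forced
# into that component)
.profile_site_loglik <- function(tree, data, profile, rho, alpha, ncat) {
  mod <- aa_model("cat-f81", alpha = alpha, ncat = ncat,
                  profiles = list(profile / sum(profile)))
  mod$rho <- rho
  pruning_loglik(tree, data, mod, per_site = TRUE)
}

#' One Gibbs sweep over CAT site allocations
#'
#' Resamples every site's component from its full conditional under the
#' Dirichlet process: existing components enter proportionally to their
#' occupancy times the site likelihood; `m_aux` fresh components drawn
#' from the base measure stand in for the prior-predictive term
#' (auxiliary-component sampling). Emptied components are dropped.
#'
#' @param state A `"cf_cat_state"`.
#' @param tree,data Tree and character matrix for the likelihood.
#' @param rho Shared exchangeability matrix (uniform for CAT-F81).
#' @param alpha,ncat Gamma rate-heterogeneity parameters.
#' @param m_aux Number of auxiliary components (default 3).
#' @return Updated `"cf_cat_state"`.
#' @export
cat_gibbs_sweep <- function(state, tree, data, rho = uniform_exchangeabilities(),
                            alpha = 1, ncat = 4L, m_aux = 3L) {
  nsites <- length(state$site_comp)
  sitell <- function(p) .profile_site_loglik(tree, data, p, rho, alpha, ncat)
  # candidate pool: real components followed by m_aux auxiliary draws from
  # the base measure; a promoted auxiliary is replaced by a fresh draw
  profiles <- state$profiles
  k <- length(profiles)
  aux <- lapply(seq_len(m_aux), function(i) .rdirichlet(rep(state$base_alpha, 20)))
  ll <- vapply(c(profiles, aux), sitell, numeric(nsites))
  ll <- matrix(ll, nrow = nsites)
  counts <- tabulate(state$site_comp, nbins = k)
  alloc <- state$site_comp
  for (i in seq_len(nsites)) {
    counts[alloc[i]] <- counts[alloc[i]] - 1L
    logw <- c(ifelse(counts > 0, log(counts), -Inf) + ll[i, seq_len(k)],
              log(state$conc / m_aux) + ll[i, k + seq_len(m_aux)])
    w <- exp(logw - max(logw))
    pick <- sample.int(k + m_aux, 1L, prob = w / sum(w))
    if (pick > k) {
      j <- pick - k
      profiles[[k + 1L]] <- aux[[j]]
      counts <- c(counts, 0L)
      # splice promoted column into the real block, refresh the aux slot
      aux[[j]] <- .rdirichlet(rep(state$base_alpha, 20))
      newcol <- ll[, pick, drop = FALSE]
      ll[, pick] <- sitell(aux[[j]])
      ll <- cbind(ll[, seq_len(k), drop = FALSE], newcol,
                  ll[, k + seq_len(m_aux), drop = FALSE])
      k <- k + 1L
      pick <- k
    }
    alloc[i] <- pick
    counts[pick] <- counts[pick] + 1L
  }
  keep <- which(tabulate(alloc, nbins = k) > 0L)
  state$profiles <- profiles[keep]
  state$site_comp <- match(alloc, keep)
  state
}

#' Metropolis update of the CAT component profiles
#'
#' Each component's profile gets a Dirichlet proposal centred on the
#' current profile; the acceptance ratio combines the site likelihoods of
#' the component's sites, the symmetric-Dirichlet base measure, and the
#' proposal Hastings correction, preserving detailed balance.
#'
#' @inheritParams cat_gibbs_sweep
#' @param kappa Proposal concentration (larger = smaller steps).
#' @return Updated state; attribute `accept` holds per-component 0/1.
#' @export
sample_component_profiles <- function(state, tree, data,
                                      rho = uniform_exchangeabilities(),
                                      alpha = 1, ncat = 4L, kappa = 200) {
  acc <- numeric(length(state$profiles))
  aa_idx <- match(data, aa_states())
  dim(aa_idx) <- dim(data)
  # each site contributes total weight 1, split over its observed
  # residues, so the proposal's concentration matches the posterior's
  # (one profile draw per site), not the raw cell count
  site_counts <- function(sites) {
    out <- numeric(20L)
    for (s in sites) {
      idx <- aa_idx[, s]
      idx <- idx[!is.na(idx)]
      if (length(idx)) {
        tb <- tabulate(idx, nbins = 20L)
        out <- out + tb / length(idx)
      }
    }
    out
  }
  for (c in seq_along(state$profiles)) {
    cur <- state$profiles[[c]]
    sites <- which(state$site_comp == c)
    # alternate a local Dirichlet random walk with an empirical
    # independence proposal centred on the component's residue counts
    # (near-conjugate, hence fast-mixing; the Hastings term keeps the
    # chain exact either way)
    if (runif(1) < 0.5) {
      prop <- .rdirichlet(kappa * cur + 0.05)
      hast <- .ddirichlet_log(cur, kappa * prop + 0.05) -
        .ddirichlet_log(prop, kappa * cur + 0.05)
    } else {
      a_emp <- state$base_alpha + site_counts(sites)
      prop <- .rdirichlet(a_emp)
      hast <- .ddirichlet_log(cur, a_emp) - .ddirichlet_log(prop, a_emp)
    }
    ll_cur <- sum(.profile_site_loglik(tree, data, cur, rho, alpha, ncat)[sites])
    ll_prop <- sum(.profile_site_loglik(tree, data, prop, rho, alpha, ncat)[sites])
    prior <- .ddirichlet_log(prop, rep(state$base_alpha, 20)) -
      .ddirichlet_log(cur, rep(state$base_alpha, 20))
    if (.mh_accept(ll_prop - ll_cur + prior + hast)) {
      state$profiles[[c]] <- prop
      acc[c] <- 1
    }
  }
  attr(state, "accept") <- acc
  state
}

# MH update of the DP concentration under an exponential hyperprior
# (mean 10); allocation likelihood conc^K Gamma(conc)/Gamma(conc + n).
.cat_update_conc <- function(state, prior_mean = 10) {
  n <- length(state$site_comp)
  k <- length(state$profiles)
  logp <- function(a) {
    if (a <= 0) return(-Inf)
    k * log(a) + lgamma(a) - lgamma(a + n) - a / prior_mean
  }
  prop <- state$conc * exp(runif(1, -0.5, 0.5))
  if (.mh_accept(logp(prop) - logp(state$conc) + log(prop / state$conc))) {
    state$conc <- prop
  }
  state
}
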