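# Amino-acid substitution models: discrete-gamma rate heterogeneity,
# reversible generator construction, eigen machinery, and the model-spec
# object consumed by the likelihood engine.

#' Discrete-gamma rate categories
#'
#' Equal-probability discretization of Gamma(shape = alpha, rate = alpha)
#' (mean 1). Category rates are the conditional bin means by default
#' (bin medians behind the `method` flag), renormalized so the weighted
#' mean is exactly 1.
#'
#' @param alpha Shape parameter, > 0.
#' @param ncat Number of categories (default 4).
#' @param method `"mean"` (default) or `"median"`.
#' @return List with `rates` (increasing, length `ncat`) and `weights`
#'   (all `1/ncat`).
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  k <- seq_len(ncat)
  if (method == "mean") {
    # E[X | q_{k-1} < X <= q_k] for X ~ Gamma(a, a): uses the identity
    # integral x f_a(x) = P(Gamma(a+1, a) <= q)
    bounds <- qgamma(k / ncat, shape = alpha, rate = alpha)
    upper <- pgamma(bounds, shape = alpha + 1, rate = alpha)
    lower <- c(0, head(upper, -1L))
    rates <- (upper - lower) * ncat
  } else {
    rates <- qgamma((k - 0.5) / ncat, shape = alpha, rate = alpha)
  }
  rates <- rates / mean(rates)
  list(rates = rates, weights = rep(1 / ncat, ncat))
}

#' Build a scaled reversible rate matrix
#'
#' `Q[i,j] = rho[i,j] * pi[j]` off-diagonal, rows summing to zero, scaled
#' to one expected substitution per unit branch length
#' (`-sum(pi * diag(Q)) = 1`). Satisfies detailed balance
#' `pi[i] Q[i,j] = pi[j] Q[j,i]`.
#'
#' @param rho Symmetric non-negative 20x20 exchangeability matrix.
#' @param pi Equilibrium frequencies (length 20, sums to 1; zeros allowed).
#' @return 20x20 generator matrix.
#' @export
build_rate_matrix <- function(rho, pi) {
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho),
            length(pi) == nrow(rho), all(pi >= 0))
  if (max(abs(rho - t(rho))) > 1e-12) stop("rho must be symmetric")
  pi <- pi / sum(pi)
  Q <- rho * rep(pi, each = nrow(rho))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (zero total rate)")
  Q / scale
}

# Eigen machinery for reversible Q: symmetrize with D = diag(sqrt(pi)),
# eigendecompose, keep A = D^-1 U and B = U' D so P(t) = A exp(Lt) B.
# States with pi == 0 are held absorbing-invisible via a tiny floor.
.eigen_q <- function(Q, pi) {
  pi <- pi / sum(pi)
  pif <- pmax(pi, 1e-12)
  d <- sqrt(pif)
  S <- Q * (d / rep(d, each = length(d)))  # diag(d) Q diag(1/d), elementwise
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / d, B = t(e$vectors) * rep(d, each = length(d)),
       values = e$values, pi = pi)
}

# P(t) from an .eigen_q decomposition; clamps numerical negatives.
.prob_matrix <- function(eig, t) {
  P <- eig$A %*% (exp(eig$values * t) * eig$B)
  P[P < 0] <- 0
  P
}

#' Specify an amino-acid substitution model
#'
#' Bundles the exchangeability scheme, equilibrium frequencies (or CAT
#' profile mixture), and discrete-gamma rate heterogeneity into the object
#' consumed by [pruning_loglik()] and the samplers.
#'
#' @param name One of `"poisson"`, `"lg"`, `"wag"`, `"gtr"`, `"cat-f81"`,
#'   `"cat-gtr"`.
#' @param alpha Gamma shape; `ncat = 1` disables rate heterogeneity.
#' @param ncat Number of gamma categories (default 4).
#' @param rho Exchangeabilities for `"gtr"`/`"cat-gtr"` (default: uniform
#'   start).
#' @param freqs Equilibrium frequencies for site-homogeneous models
#'   (default: the empirical matrix's frequencies; uniform for poisson/gtr).
#' @param profiles For CAT models, a list of frequency vectors (mixture
#'   components).
#' @param site_comp For CAT models, integer allocation of sites to
#'   components (1-based); may be `NULL` until data are attached.
#' @return Object of class `"cf_model"`.
#' @export
aa_model <- function(name = c("poisson", "lg", "wag", "gtr", "cat-f81", "cat-gtr"),
                     alpha = 1, ncat = 4L, rho = NULL, freqs = NULL,
                     profiles = NULL, site_comp = NULL) {
  name <- match.arg(name)
  unif <- rep(1 / 20, 20)
  if (name %in% c("lg", "wag")) {
    emp <- .empirical_model(name)
    if (is.null(rho)) rho <- emp$rho
    if (is.null(freqs)) freqs <- emp$freqs
  } else if (name %in% c("poisson", "cat-f81")) {
    rho <- uniform_exchangeabilities()
    if (is.null(freqs)) freqs <- unif
  } else { # gtr, cat-gtr
    if (is.null(rho)) rho <- uniform_exchangeabilities()
    if (is.null(freqs)) freqs <- unif
  }
  is_cat <- startsWith(name, "cat")
  if (is_cat && is.null(profiles)) profiles <- list(unif)
  structure(list(name = name, alpha = alpha, ncat = as.integer(ncat),
                 rho = rho, freqs = freqs / sum(freqs),
                 is_cat = is_cat, profiles = profiles,
                 site_comp = site_comp),
            class = "cf_model")
}

#' @export
print.cf_model <- function(x, ...) {
  cat(sprintf("<cf_model> %s + G%d (alpha = %.3g)%s\n", toupper(x$name),
              x$ncat, x$alpha,
              if (x$is_cat) paste0(", ", length(x$profiles), " profile(s)")
              else ""))
  invisible(x)
}

# Component list for the engine: one eigen system per mixture component.
# Site-homogeneous models are a single component.
.model_components <- function(model, nsites) {
  if (model$is_cat) {
    comps <- lapply(model$profiles, function(p) {
      p <- p / sum(p)
      .eigen_q(build_rate_matrix(model$rho, p), p)
    })
    sc <- model$site_comp
    if (is.null(sc)) sc <- rep(1L, nsites)
    stopifnot(length(sc) == nsites, all(sc >= 1L), all(sc <= length(comps)))
    list(comps = comps, site_comp = as.integer(sc))
  } else {
    list(comps = list(.eigen_q(build_rate_matrix(model$rho, model$freqs),
                               model$freqs)),
         site_comp = rep(1L, nsites))
  }
}

# Encode a character data matrix (taxa x sites) to 0..19 / -1L.
.encode_states <- function(m) {
  idx <- match(m, aa_states()) - 1L
  idx[is.na(idx)] <- -1L
  dim(idx) <- dim(m)
  rownames(idx) <- rownames(m)
  idx
}
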