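# Relaxed molecular-clock priors, birth-death node-age prior, soft fossil
# calibrations, and the exponential root-age prior. Time is in Mya before
# present; tips sit at age 0.

#' Specify a clock model
#'
#' @param kind `"cl"` (strict), `"ln"` (autocorrelated log-normal), or
#'   `"ugam"` (uncorrelated gamma branch rates).
#' @param mu_r Global mean rate, substitutions/site/Mya (> 0).
#' @param sigma2 LN autocorrelation variance per Mya (>= 0).
#' @param nu UGAM relative rate variance (>= 0): branch rates are i.i.d.
#'   Gamma with mean `mu_r` and variance `nu * mu_r^2`.
#' @param root_spread SD of log root rate around `log(mu_r)` under LN.
#' @return Object of class `"cf_clock"`.
#' @export
clock_model <- function(kind = c("ln", "ugam", "cl"), mu_r = 1e-3,
                        sigma2 = 0.1, nu = 0.5, root_spread = 0.5) {
  kind <- match.arg(kind)
  stopifnot(mu_r > 0, sigma2 >= 0, nu >= 0, root_spread > 0)
  structure(list(kind = kind, mu_r = mu_r, sigma2 = sigma2, nu = nu,
                 root_spread = root_spread),
            class = "cf_clock")
}

#' @export
print.cf_clock <- function(x, ...) {
  cat(sprintf("<cf_clock> %s (mu_r = %.3g%s)\n", toupper(x$kind), x$mu_r,
              switch(x$kind,
                     ln = sprintf(", sigma2 = %.3g", x$sigma2),
                     ugam = sprintf(", nu = %.3g", x$nu), "")))
  invisible(x)
}

#' Log density of node rates under the autocorrelated log-normal clock
#'
#' Child log-rates are normal around the parent log-rate with variance
#' `sigma2 * dt` and mean shifted by `-sigma2 * dt / 2` so that
#' `E[r_child | r_parent] = r_parent`; the root rate is log-normal around
#' `mu_r`.
#'
#' @param rates Positive per-node rates indexed by node id.
#' @param tree Ultrametric `"phylo"` (chronogram).
#' @param ages Node ages (from [node_ages()]); computed if `NULL`.
#' @param clock A `"ln"` [clock_model()].
#' @return Log density; `-Inf` for non-positive rates.
#' @export
ln_clock_logdensity <- function(rates, tree, clock, ages = NULL) {
  if (any(!is.finite(rates)) || any(rates <= 0)) return(-Inf)
  if (is.null(ages)) ages <- node_ages(tree)
  root <- length(tree$tip.label) + 1L
  ld <- dnorm(log(rates[root]), log(clock$mu_r), clock$root_spread, log = TRUE) -
    log(rates[root])
  s2 <- clock$sigma2
  p <- tree$edge[, 1L]; v <- tree$edge[, 2L]
  lrp <- log(rates[p]); lrv <- log(rates[v])
  if (s2 == 0) {
    return(if (max(abs(lrv - lrp)) > 1e-12) -Inf else ld)
  }
  dt <- ages[p] - ages[v]
  if (any(dt <= 0)) return(-Inf)
  ld + sum(dnorm(lrv, lrp - s2 * dt / 2, sqrt(s2 * dt), log = TRUE) - lrv)
}

#' Log density of branch rates under the uncorrelated gamma clock
#'
#' Branch rates i.i.d. Gamma(shape `1/nu`, scale `nu * mu_r`): mean
#' `mu_r`, variance `nu * mu_r^2`.
#'
#' @param branch_rates Positive per-branch rates.
#' @param clock A `"ugam"` [clock_model()].
#' @return Log density; with `nu = 0` delegates to the strict clock
#'   (point mass at `mu_r`: 0 when all rates equal `mu_r`, else `-Inf`).
#' @export
ugam_clock_logdensity <- function(branch_rates, clock) {
  if (any(!is.finite(branch_rates)) || any(branch_rates <= 0)) return(-Inf)
  if (clock$nu == 0) {
    return(if (all(abs(branch_rates - clock$mu_r) < 1e-12)) 0 else -Inf)
  }
  shape <- 1 / clock$nu
  scale <- clock$nu * clock$mu_r
  sum(dgamma(branch_rates, shape = shape, scale = scale, log = TRUE))
}

# ---- birth-death node-age prior --------------------------------------

# CDF kernel q(t) = (1 - exp(-r t)) / (lambda - mu exp(-r t)), r = la - mu;
# conditioned on root age T, non-root internal ages are i.i.d. with
# density q'(t) / q(T) on (0, T).
.bd_q <- function(t, lambda, mu) {
  r <- lambda - mu
  if (r <= 0) stop("requires lambda > mu")
  if (mu == 0) return((1 - exp(-lambda * t)) / lambda)
  (1 - exp(-r * t)) / (lambda - mu * exp(-r * t))
}

.bd_logdens <- function(t, lambda, mu, root_age) {
  r <- lambda - mu
  log(r^2) - r * t - 2 * log(lambda - mu * exp(-r * t)) -
    log(.bd_q(root_age, lambda, mu))
}

# inverse CDF on (0, T)
.bd_quantile <- function(p, lambda, mu, root_age) {
  r <- lambda - mu
  qT <- .bd_q(root_age, lambda, mu)
  y <- p * qT
  # solve (1 - e) = y (lambda - mu e), e = exp(-r t)
  e <- (1 - y * lambda) / (1 - y * mu)
  -log(e) / r
}

#' Log density of internal node ages under the conditioned birth-death prior
#'
#' Joint density of the non-root internal node ages given the root age,
#' the taxon count, and the labelled topology: i.i.d. conditioned
#' speciation ages with an ordering indicator (parent older than child).
#'
#' @param tree Rooted topology (`"phylo"`); branch lengths ignored.
#' @param ages Node ages indexed by node id (tips 0).
#' @param lambda,mu Birth and death rates per lineage per Mya
#'   (`lambda > mu >= 0`).
#' @return Log density; `-Inf` if any parent is not older than its child or
#'   any tip age is nonzero.
#' @export
birthdeath_ages_logdensity <- function(tree, ages, lambda, mu) {
  stopifnot(lambda > mu, mu >= 0)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (any(abs(ages[seq_len(ntip)]) > 1e-9)) return(-Inf)
  if (any(ages[tree$edge[, 1L]] <= ages[tree$edge[, 2L]])) return(-Inf)
  internal <- setdiff((ntip + 1L):(ntip + tree$Nnode), root)
  if (!length(internal)) return(0)
  sum(.bd_logdens(ages[internal], lambda, mu, ages[root]))
}

# ---- calibrations -----------------------------------------------------

#' Construct a soft calibration constraint
#'
#' Soft min/max age bounds on a clade: flat on the plateau, exponential
#' tails outside carrying probability mass `eps` per constrained side.
#' Tail scales are set from the plateau width so that, read as a density,
#' the plateau carries `1 - 2 eps` (two-sided) or `1 - eps` (one-sided)
#' of the mass. One-sided constraints use the bound's own age as the
#' reference width.
#'
#' @param clade Name of the constraint.
#' @param taxa Character vector of taxa whose MRCA the constraint binds.
#' @param min_age,max_age Bounds in Mya (`NA` = unbounded on that side).
#' @param eps Tail mass per constrained side, in (0, 0.5).
#' @return Object of class `"cf_calibration"`.
#' @export
calibration <- function(clade, taxa, min_age = NA, max_age = NA,
                        eps = 0.025) {
  stopifnot(eps > 0, eps < 0.5)
  if (!is.na(min_age) && !is.na(max_age) && min_age >= max_age) {
    stop("min_age must be < max_age")
  }
  if (is.na(min_age) && is.na(max_age)) stop("at least one bound required")
  two_sided <- !is.na(min_age) && !is.na(max_age)
  width <- if (two_sided) max_age - min_age
           else if (!is.na(min_age)) min_age else max_age
  plateau_mass <- if (two_sided) 1 - 2 * eps else 1 - eps
  scale <- eps * width / plateau_mass  # tail integral = eps * plateau height^-1
  structure(list(clade = clade, taxa = taxa, min_age = min_age,
                 max_age = max_age, eps = eps, width = width,
                 tail_scale = scale),
            class = "cf_calibration")
}

#' Log multiplicative factor of a soft calibration at a given age
#'
#' 0 on the plateau (between the bounds); linear-in-age exponential decay
#' outside, continuous at the bounds.
#'
#' @param age Node age (Mya), vectorized.
#' @param cal A [calibration()].
#' @return Log factor (<= 0).
#' @export
calibration_logfactor <- function(age, cal) {
  lf <- numeric(length(age))
  if (!is.na(cal$min_age)) {
    below <- age < cal$min_age
    lf[below] <- -(cal$min_age - age[below]) / cal$tail_scale
  }
  if (!is.na(cal$max_age)) {
    above <- age > cal$max_age
    lf[above] <- -(age[above] - cal$max_age) / cal$tail_scale
  }
  lf
}

#' Read a calibration table
#'
#' TSV with columns `clade_name`, `taxa` (comma-separated), `min_age`,
#' `max_age` (empty = unbounded), `tail_prob`.
#'
#' @param path File path; default is the packaged 13-constraint fixture
#'   transcribing the study-style vertebrate + echinoderm calibrations.
#' @return List of [calibration()] objects.
#' @export
read_calibrations <- function(path = system.file("extdata",
                                                 "calibrations_deutero13.tsv",
                                                 package = "chronoforge")) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("", "NA"))
  lapply(seq_len(nrow(tab)), function(i) {
    calibration(tab$clade_name[i],
                strsplit(tab$taxa[i], ",")[[1]],
                min_age = tab$min_age[i], max_age = tab$max_age[i],
                eps = tab$tail_prob[i])
  })
}

#' Exponential root-age prior
#'
#' @param mean Prior mean in Mya (default 540).
#' @return Object of class `"cf_rootprior"`.
#' @export
root_prior <- function(mean = 540) {
  stopifnot(mean > 0)
  structure(list(mean = mean), class = "cf_rootprior")
}

#' Log density of the root-age prior
#'
#' @param age Root age (Mya).
#' @param prior A [root_prior()].
#' @return `-log(mean) - age/mean`; `-Inf` for negative ages.
#' @export
root_prior_logdensity <- function(age, prior) {
  ifelse(age < 0, -Inf, -log(prior$mean) - age / prior$mean)
}

# Map calibrations onto node ids of a tree; errors if anchor taxa missing.
.attach_calibrations <- function(tree, calibrations) {
  vapply(calibrations, function(cal) {
    taxa <- intersect(cal$taxa, tree$tip.label)
    if (length(taxa) < 1L) {
      stop("calibration '", cal$clade, "': no anchor taxa in tree")
    }
    if (length(taxa) == 1L) match(taxa, tree$tip.label)
    else as.integer(ape::getMRCA(tree, taxa))
  }, integer(1))
}
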