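# Shared MCMC scaffolding: chain configuration, the posterior-trace
# container, and small Metropolis helpers used by both samplers.

#' Configure an MCMC chain
#'
#' @param cycles Number of cycles; one cycle is a full sweep of the move
#'   schedule.
#' @param thin Record every `thin`-th cycle.
#' @param burnin Number of *recorded samples* to discard in summaries.
#' @param seed Integer RNG seed; chain id offsets it.
#' @param moves Optional named numeric vector of per-cycle move-schedule
#'   weights overriding the defaults (`branch`/`ages`, `topology`, `cat`,
#'   `hyper`).
#' @return Object of class `"cf_config"`.
#' @export
chain_config <- function(cycles, thin = 1L, burnin = 0L, seed = 1L,
                         moves = NULL) {
  stopifnot(cycles >= 1L, thin >= 1L, burnin >= 0L)
  retained <- floor(cycles / thin)
  if (burnin >= retained) stop("burn-in (", burnin,
                               ") must be smaller than recorded samples (",
                               retained, ")")
  structure(list(cycles = as.integer(cycles), thin = as.integer(thin),
                 burnin = as.integer(burnin), seed = as.integer(seed),
                 moves = moves),
            class = "cf_config")
}

# log Metropolis acceptance
.mh_accept <- function(log_ratio) {
  is.finite(log_ratio) && (log_ratio >= 0 || log(runif(1)) < log_ratio)
}

# Dirichlet sampling / log density (used by GTR and CAT profile moves)
.rdirichlet <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  x / sum(x)
}
.ddirichlet_log <- function(x, alpha) {
  if (any(x <= 0)) return(-Inf)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

#' Posterior trace object
#'
#' Assembled by the samplers; not usually called directly.
#'
#' @param mode `"phylogram"` or `"chronogram"`.
#' @param scalars Data frame of per-sample scalar parameters (cycle, lnL,
#'   lnPrior, ...).
#' @param trees List of sampled trees (phylogram mode) or `NULL`.
#' @param ages Matrix of sampled node ages (chronogram mode) or `NULL`.
#' @param rates Matrix of sampled per-node (or per-branch) rates or `NULL`.
#' @param tree Fixed topology (chronogram mode).
#' @param config The [chain_config()] used.
#' @param model,clock Model specifications.
#' @return Object of class `"cf_trace"`.
#' @export
posterior_trace <- function(mode, scalars, trees = NULL, ages = NULL,
                            rates = NULL, tree = NULL, config = NULL,
                            model = NULL, clock = NULL, models = NULL) {
  structure(list(mode = mode, scalars = scalars, trees = trees, ages = ages,
                 rates = rates, tree = tree, config = config, model = model,
                 clock = clock, models = models),
            class = "cf_trace")
}

#' @export
print.cf_trace <- function(x, ...) {
  cat(sprintf("<cf_trace> %s mode, %d samples (thin %d, burn-in %d)\n",
              x$mode, nrow(x$scalars),
              if (!is.null(x$config)) x$config$thin else NA_integer_,
              if (!is.null(x$config)) x$config$burnin else 0L))
  if (nrow(x$scalars)) {
    post <- trace_retained(x)
    cat("  post-burn-in lnL: mean", signif(mean(post$scalars$lnL), 6), "\n")
  }
  invisible(x)
}

#' Post-burn-in portion of a trace
#'
#' @param trace A `"cf_trace"`.
#' @param burnin Override the stored burn-in (number of samples).
#' @return A `"cf_trace"` restricted to retained samples.
#' @export
trace_retained <- function(trace, burnin = NULL) {
  if (is.null(burnin)) burnin <- if (!is.null(trace$config)) trace$config$burnin else 0L
  n <- nrow(trace$scalars)
  if (burnin >= n) stop("trace shorter than burn-in")
  keep <- (burnin + 1L):n
  trace$scalars <- trace$scalars[keep, , drop = FALSE]
  if (!is.null(trace$trees)) trace$trees <- trace$trees[keep]
  if (!is.null(trace$ages)) trace$ages <- trace$ages[keep, , drop = FALSE]
  if (!is.null(trace$rates)) trace$rates <- trace$rates[keep, , drop = FALSE]
  if (!is.null(trace$models)) trace$models <- trace$models[keep]
  trace$config$burnin <- 0L
  trace
}

#' Two-chain convergence report
#'
#' Compares clade frequencies of sampled topologies (bpcomp-style
#' `max_diff`) and scalar-parameter means between two chains.
#'
#' @param trace_a,trace_b Two `"cf_trace"` objects from the same model.
#' @param burnin Samples to discard from each (default: stored burn-in).
#' @param max_diff_threshold Pass threshold for clade `max_diff`
#'   (default 0.3).
#' @param scalar_threshold Pass threshold for the relative difference of
#'   scalar means (default 0.1).
#' @return List with `max_diff`, `scalar_discrepancy` (named), `pass`.
#' @export
convergence_report <- function(trace_a, trace_b, burnin = NULL,
                               max_diff_threshold = 0.3,
                               scalar_threshold = 0.1) {
  a <- trace_retained(trace_a, burnin)
  b <- trace_retained(trace_b, burnin)
  md <- if (!is.null(a$trees) && !is.null(b$trees)) {
    max_clade_support_diff(a$trees, b$trees)
  } else NA_real_
  common <- intersect(names(a$scalars), names(b$scalars))
  common <- setdiff(common, "cycle")
  disc <- vapply(common, function(p) {
    ma <- mean(a$scalars[[p]]); mb <- mean(b$scalars[[p]])
    den <- max(abs(ma), abs(mb), 1e-12)
    abs(ma - mb) / den
  }, numeric(1))
  pass <- (is.na(md) || md < max_diff_threshold) &&
    all(disc < scalar_threshold)
  list(max_diff = md, scalar_discrepancy = disc, pass = pass)
}
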