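# User-facing fitting interface: multi-chain wrappers around the samplers
# returning classed fits with print / summary / coef / plot methods.

#' Run one MCMC chain (generic dispatcher)
#'
#' Thin dispatcher over [run_phylogram_chain()] (topology + branch
#' lengths) and [run_dating_chain()] (fixed-topology dating).
#'
#' @param data Character matrix or [concatenate()] result.
#' @param model An [aa_model()].
#' @param config A [chain_config()].
#' @param mode `"phylogram"` or `"chronogram"`.
#' @param ... Passed to the mode-specific sampler (e.g. `tree`, `clock`,
#'   `calibrations` for chronogram mode).
#' @return A `"cf_trace"`.
#' @export
run_chain <- function(data, model, config, mode = c("phylogram", "chronogram"),
                      ...) {
  mode <- match.arg(mode)
  if (mode == "phylogram") {
    run_phylogram_chain(data, model, config, ...)
  } else {
    run_dating_chain(data = data, model = model, config = config, ...)
  }
}

#' Bayesian phylogram inference
#'
#' Runs independent MCMC chains over topology, branch lengths, and model
#' parameters, checks convergence bpcomp-style, and reports the combined
#' 50% majority-rule consensus with posterior probabilities.
#'
#' @param data Character matrix (taxa x sites) or [concatenate()] result.
#' @param model An [aa_model()] (default LG + G4).
#' @param cycles,thin,burnin Chain schedule (burn-in in recorded samples).
#' @param chains Number of independent chains (default 2).
#' @param seed Integer seed; chain id offsets it.
#' @param ... Passed to [run_phylogram_chain()].
#' @return Object of class `"cf_fit"`: `consensus` (supports as node
#'   labels), `traces`, `convergence`, `config`.
#' @export
infer_phylogeny <- function(data, model = aa_model("lg"), cycles = 1000L,
                            thin = 1L, burnin = 200L, chains = 2L,
                            seed = 1L, ...) {
  config <- chain_config(cycles, thin = thin, burnin = burnin, seed = seed)
  traces <- lapply(seq_len(chains), function(i) {
    run_phylogram_chain(data, model, config, chain_id = i, ...)
  })
  conv <- if (chains >= 2L) convergence_report(traces[[1L]], traces[[2L]])
          else NULL
  combined <- unlist(lapply(traces, function(tr) trace_retained(tr)$trees),
                     recursive = FALSE)
  cons <- majority_rule_consensus(combined)
  structure(list(consensus = cons, traces = traces, convergence = conv,
                 config = config, model = model),
            class = "cf_fit")
}

#' @export
print.cf_fit <- function(x, ...) {
  n <- sum(vapply(x$traces, function(tr) {
    nrow(trace_retained(tr)$scalars)
  }, numeric(1)))
  cat(sprintf("<cf_fit> consensus over %d post-burn-in trees (%d chains)\n",
              n, length(x$traces)))
  if (!is.null(x$convergence)) {
    cat(sprintf("  bpcomp max_diff = %.3f (%s)\n", x$convergence$max_diff,
                if (x$convergence$pass) "converged" else "NOT converged"))
  }
  cat("  consensus:", write_newick(x$consensus), "\n")
  invisible(x)
}

#' @export
summary.cf_fit <- function(object, ...) {
  combined <- unlist(lapply(object$traces,
                            function(tr) trace_retained(tr)$trees),
                     recursive = FALSE)
  list(clade_support = clade_frequencies(combined),
       convergence = object$convergence,
       lnL = mean(unlist(lapply(object$traces, function(tr) {
         trace_retained(tr)$scalars$lnL
       }))))
}

#' @export
coef.cf_fit <- function(object, ...) {
  post <- do.call(rbind, lapply(object$traces, function(tr) {
    trace_retained(tr)$scalars
  }))
  c(alpha = mean(post$alpha), tree_length = mean(post$tree_length))
}

#' @export
plot.cf_fit <- function(x, ...) {
  ape::plot.phylo(x$consensus, show.node.label = TRUE, ...)
  invisible(x)
}

#' Bayesian divergence-time estimation
#'
#' Fixed-topology relaxed-clock dating: runs independent chains, pools
#' post-burn-in samples, and summarizes clade ages.
#'
#' @param tree Rooted topology (`"phylo"`).
#' @param data Character matrix (taxa x sites).
#' @param model Fixed-parameter [aa_model()].
#' @param clock A [clock_model()].
#' @param calibrations List of [calibration()]s.
#' @param rprior A [root_prior()].
#' @param cycles,thin,burnin Chain schedule.
#' @param chains Number of chains.
#' @param seed Integer seed.
#' @param ... Passed to [run_dating_chain()].
#' @return Object of class `"cf_dating"`: `dates` (a `"cf_dates"` table),
#'   `traces`, `convergence`, `tree`.
#' @export
infer_dates <- function(tree, data, model = aa_model("poisson"),
                        clock = clock_model("ln"), calibrations = list(),
                        rprior = root_prior(540), cycles = 2000L,
                        thin = 2L, burnin = 200L, chains = 2L, seed = 1L,
                        ...) {
  config <- chain_config(cycles, thin = thin, burnin = burnin, seed = seed)
  traces <- lapply(seq_len(chains), function(i) {
    run_dating_chain(tree, data = data, model = model, clock = clock,
                     calibrations = calibrations, rprior = rprior,
                     config = config, chain_id = i, ...)
  })
  conv <- if (chains >= 2L) convergence_report(traces[[1L]], traces[[2L]])
          else NULL
  pooled <- traces[[1L]]
  pooled$scalars <- do.call(rbind, lapply(traces, function(tr) {
    trace_retained(tr)$scalars
  }))
  pooled$ages <- do.call(rbind, lapply(traces, function(tr) {
    trace_retained(tr)$ages
  }))
  pooled$rates <- do.call(rbind, lapply(traces, function(tr) {
    trace_retained(tr)$rates
  }))
  pooled$config$burnin <- 0L
  structure(list(dates = summarize_node_ages(pooled), pooled = pooled,
                 traces = traces, convergence = conv, tree = tree,
                 clock = clock),
            class = "cf_dating")
}

#' @export
print.cf_dating <- function(x, ...) {
  cat(sprintf("<cf_dating> %s clock, %d clades dated\n",
              toupper(x$clock$kind), nrow(x$dates)))
  print(x$dates)
  invisible(x)
}

#' @export
summary.cf_dating <- function(object, ...) {
  list(dates = object$dates, rates = terminal_rates(object$pooled),
       convergence = object$convergence)
}

#' @export
coef.cf_dating <- function(object, ...) {
  setNames(object$dates$mean, object$dates$clade)
}

#' @export
plot.cf_dating <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  nnode <- ntip + x$tree$Nnode
  ages <- numeric(nnode)
  ages[(ntip + 1L):nnode] <- x$dates$mean
  chrono <- .tree_with_ages(x$tree, ages)
  ape::plot.phylo(chrono, ...)
  ape::axisPhylo()
  invisible(x)
}
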