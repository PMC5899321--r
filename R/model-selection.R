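# Bayesian cross-validation: random learning/test site splits, predictive
# log-likelihood scores from a learning-set posterior, and paired model
# comparison.

#' Draw cross-validation site splits
#'
#' Uniform sampling without replacement of disjoint learning and test site
#' sets, replicated; reproducible under a fixed seed. Specify either fixed
#' counts (`train`, `test`) or `fractions` (e.g. `c(0.9, 0.1)`, in which
#' case the learning size is `round(frac * n_sites)` and the test set is
#' the complement fraction of the remaining sites).
#'
#' @param n_sites Number of sites in the matrix.
#' @param train,test Fixed site counts, or `NULL` when using `fractions`.
#' @param fractions Length-2 numeric (learning, test), summing to <= 1.
#' @param replicates Number of replicate splits (default 10).
#' @param seed Integer seed.
#' @return List of splits, each `list(id, train, test, seed)` with
#'   1-based site indices.
#' @export
make_cv_splits <- function(n_sites, train = NULL, test = NULL,
                           fractions = NULL, replicates = 10L, seed = 1L) {
  if (is.null(train) != is.null(test)) {
    stop("specify both train and test, or fractions")
  }
  if (!is.null(fractions)) {
    stopifnot(length(fractions) == 2L, sum(fractions) <= 1 + 1e-9)
    train <- round(fractions[1L] * n_sites)
    test <- round(fractions[2L] * n_sites)
    if (train + test > n_sites) test <- n_sites - train
  }
  if (is.null(train)) stop("no split scheme given")
  if (train + test > n_sites) {
    stop("train + test (", train + test, ") exceeds n_sites (", n_sites, ")")
  }
  stopifnot(train >= 1L, test >= 1L)
  .with_seed(seed, {
    lapply(seq_len(replicates), function(i) {
      idx <- sample.int(n_sites, train + test)
      list(id = i, train = sort(idx[seq_len(train)]),
           test = sort(idx[train + seq_len(test)]), seed = seed)
    })
  })
}

#' Predictive log-likelihood score on held-out sites
#'
#' The cross-validation score: the log of the posterior-sample average of
#' the test-set likelihood, `ln[(1/S) sum_s L(test | theta_s)]`, computed
#' with a running log-sum-exp. Samples come from a learning-set trace
#' (phylogram mode: sampled tree + substitution parameters; chronogram
#' mode: branch lengths induced by sampled ages and rates).
#'
#' @param trace A post-burn-in `"cf_trace"` (apply [trace_retained()]
#'   first, or pass `burnin`).
#' @param test_data Character matrix of held-out sites (taxa x sites).
#' @param burnin Optional burn-in override applied before scoring.
#' @return The predictive score (log scale).
#' @export
cv_predictive_score <- function(trace, test_data, burnin = NULL) {
  if (!is.null(burnin)) trace <- trace_retained(trace, burnin)
  S <- nrow(trace$scalars)
  if (!S) stop("empty trace")
  lls <- numeric(S)
  if (trace$mode == "phylogram") {
    for (s in seq_len(S)) {
      mod <- if (!is.null(trace$models)) trace$models[[s]] else trace$model
      lls[s] <- pruning_loglik(trace$trees[[s]], test_data, mod)
    }
  } else {
    topo <- trace$tree
    nnode <- length(topo$tip.label) + topo$Nnode
    for (s in seq_len(S)) {
      ages <- trace$ages[s, ]
      rates <- trace$rates[s, ]
      st <- list(rates = rates, branch_rates = rates)
      cl <- trace$clock
      cl$mu_r <- trace$scalars$mu_r[s]
      ltree <- topo
      ltree$edge.length <- pmax(
        .dating_branch_lengths(topo, ages, st, cl), 0)
      lls[s] <- pruning_loglik(ltree, test_data, trace$model)
    }
  }
  m <- max(lls)
  m + log(mean(exp(lls - m)))
}

#' Compare two models by paired cross-validation scores
#'
#' @param scores_a,scores_b Equal-length numeric vectors of per-replicate
#'   predictive scores, paired by split.
#' @return Object of class `"cf_cv"`: per-replicate differences
#'   (A minus B), their mean and sample SD, and the win count.
#' @export
compare_models <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score lists are unpaired (lengths ", length(scores_a), " vs ",
         length(scores_b), ")")
  }
  d <- scores_a - scores_b
  structure(list(delta = d, mean = mean(d),
                 sd = if (length(d) > 1L) sd(d) else 0,
                 wins = sum(d > 0), n = length(d)),
            class = "cf_cv")
}

#' @export
print.cf_cv <- function(x, ...) {
  cat(sprintf("<cf_cv> delta lnL = %.1f +/- %.1f (A preferred in %d/%d replicates)\n",
              x$mean, x$sd, x$wins, x$n))
  invisible(x)
}
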