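# R interface to the compiled pruning engine.

# Build an engine handle for a (tree, data, model) triple. Site-pattern
# compression (identical columns share one computation) is applied for
# site-homogeneous models; CAT models keep per-site columns because their
# allocations differ by site and change during sampling.
.make_engine <- function(tree, data, model) {
  if (inherits(data, "cf_supermatrix")) data <- data$matrix
  stopifnot(inherits(tree, "phylo"), is.matrix(data))
  missing_taxa <- setdiff(tree$tip.label, rownames(data))
  if (length(missing_taxa)) {
    stop("taxa in tree absent from matrix: ",
         paste(missing_taxa, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  elen <- numeric(nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  states <- .encode_states(data[tree$tip.label, , drop = FALSE])
  nsites <- ncol(states)
  if (!model$is_cat && nsites > 1L) {
    key <- apply(states, 2L, paste, collapse = ".")
    first <- which(!duplicated(key))
    pattern_map <- match(key, key[first])
    states <- states[, first, drop = FALSE]
    sitew <- as.numeric(tabulate(pattern_map, length(first)))
  } else {
    pattern_map <- seq_len(nsites)
    sitew <- rep(1, nsites)
  }
  npat <- ncol(states)
  mc <- .model_components(model, npat)
  if (model$is_cat && !is.null(model$site_comp)) {
    mc$site_comp <- as.integer(model$site_comp)
  }
  g <- discrete_gamma_rates(model$alpha, model$ncat)
  ptr <- engine_create(ntip, tree$edge, elen, states, mc$site_comp,
                       g$rates, g$weights, mc$comps, sitew)
  list(ptr = ptr, ntip = ntip, nnode = nnode, nsites = nsites,
       npat = npat, pattern_map = pattern_map, tree = tree, model = model)
}

# Push new gamma/mixture parameters into an engine.
.engine_update_model <- function(eng, model) {
  mc <- .model_components(model, eng$npat)
  if (model$is_cat && !is.null(model$site_comp)) {
    mc$site_comp <- as.integer(model$site_comp)
  }
  g <- discrete_gamma_rates(model$alpha, model$ncat)
  engine_set_model(eng$ptr, g$rates, g$weights, mc$comps, mc$site_comp)
  eng$model <- model
  eng
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of aligned amino-acid data on a rooted tree
#' under a reversible substitution model with discrete-gamma rate mixing
#' and, for CAT models, per-site profile components. Gap and unknown cells
#' contribute all-ones partial vectors; partials are rescaled per node to
#' avoid underflow; identical site patterns are computed once.
#'
#' @param tree Rooted `"phylo"` with branch lengths (substitutions/site).
#' @param data Character matrix (taxa x sites) or [concatenate()] result;
#'   must cover every tree tip.
#' @param model An [aa_model()].
#' @param per_site If `TRUE`, return the vector of per-site log-likelihoods
#'   (summing to the total).
#' @return Total log-likelihood (or per-site vector).
#' @export
pruning_loglik <- function(tree, data, model, per_site = FALSE) {
  eng <- .make_engine(tree, data, model)
  if (per_site) {
    engine_site_loglik(eng$ptr)[eng$pattern_map]
  } else {
    engine_loglik(eng$ptr)
  }
}
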