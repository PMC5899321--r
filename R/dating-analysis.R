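# Posterior summaries of divergence dates and lineage rates, plus the
# between-scheme and between-group comparison statistics.

#' Summarize posterior node ages
#'
#' Mean, sample SD, and central 95% credibility interval (2.5/97.5
#' empirical quantiles, linear interpolation) per clade. Clades are keyed
#' by their descendant taxon set, so summaries are robust to node
#' renumbering.
#'
#' @param trace A chronogram-mode `"cf_trace"`.
#' @param burnin Samples to discard (default: stored burn-in).
#' @param prob Credibility level (default 0.95).
#' @return Object of class `"cf_dates"`: data frame with `clade`, `taxa`,
#'   `mean`, `sd`, `lower`, `upper`.
#' @export
summarize_node_ages <- function(trace, burnin = NULL, prob = 0.95) {
  stopifnot(trace$mode == "chronogram")
  tr <- trace_retained(trace, burnin)
  if (nrow(tr$scalars) < 2L) stop("need at least 2 retained samples")
  topo <- tr$tree
  ntip <- length(topo$tip.label)
  nodes <- (ntip + 1L):(ntip + topo$Nnode)
  tips <- .descendant_tips(topo)
  a <- (1 - prob) / 2
  out <- do.call(rbind, lapply(nodes, function(v) {
    x <- tr$ages[, v]
    q <- quantile(x, c(a, 1 - a), names = FALSE, type = 7)
    data.frame(clade = paste0("node", v),
               taxa = paste(sort(tips[[v]]), collapse = ","),
               mean = mean(x), sd = sd(x), lower = q[1L], upper = q[2L],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cf_dates", "data.frame")
  out
}

#' Format a dated clade as "mean +/- SD [upper-lower]"
#'
#' The printing convention used in divergence-date tables: mean, standard
#' deviation, and the 95% interval written upper bound first.
#'
#' @param dates A `"cf_dates"` row subset (or the whole table).
#' @return Character vector.
#' @export
format_dates <- function(dates) {
  sprintf("%.0f ± %.0f[%.0f–%.0f]",
          dates$mean, dates$sd, dates$upper, dates$lower)
}

#' @export
print.cf_dates <- function(x, ...) {
  cat("<cf_dates>", nrow(x), "clades\n")
  df <- data.frame(clade = x$clade, date = format_dates(x))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Posterior mean terminal-branch rates per taxon
#'
#' For each terminal taxon, the posterior mean of its terminal-branch
#' effective rate (substitutions/site/Mya).
#'
#' @param trace A chronogram-mode `"cf_trace"`.
#' @param burnin Samples to discard.
#' @return Data frame `taxon`, `rate`.
#' @export
terminal_rates <- function(trace, burnin = NULL) {
  if (trace$mode != "chronogram") stop("terminal rates need a chronogram-mode trace")
  tr <- trace_retained(trace, burnin)
  topo <- tr$tree
  ntip <- length(topo$tip.label)
  parent_of <- integer(ntip + topo$Nnode)
  parent_of[topo$edge[, 2L]] <- topo$edge[, 1L]
  kind <- tr$clock$kind
  rate <- vapply(seq_len(ntip), function(v) {
    if (kind == "ln") {
      mean((tr$rates[, v] + tr$rates[, parent_of[v]]) / 2)
    } else {
      mean(tr$rates[, v])
    }
  }, numeric(1))
  data.frame(taxon = topo$tip.label, rate = rate, stringsAsFactors = FALSE)
}

#' Contrast evolutionary rates between two groups of taxa
#'
#' Ratio of group mean rates plus a two-sample two-tailed t test (Welch by
#' default). With a singleton group the ratio is still computed but the
#' test is skipped and flagged.
#'
#' @param rates Data frame `taxon`, `rate` (e.g. [terminal_rates()]).
#' @param group_a,group_b Character vectors of taxa.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return List with `ratio`, `t`, `p`, `test_applicable`.
#' @export
group_rate_contrast <- function(rates, group_a, group_b, var_equal = FALSE) {
  ra <- rates$rate[rates$taxon %in% group_a]
  rb <- rates$rate[rates$taxon %in% group_b]
  if (!length(ra) || !length(rb)) stop("empty group")
  ratio <- mean(ra) / mean(rb)
  if (length(ra) < 2L || length(rb) < 2L) {
    message("t test not applicable with a singleton group; ratio only")
    return(list(ratio = ratio, t = NA_real_, p = NA_real_,
                test_applicable = FALSE))
  }
  tt <- t.test(ra, rb, var.equal = var_equal)
  list(ratio = ratio, t = unname(tt$statistic), p = tt$p.value,
       test_applicable = TRUE)
}

#' Compare mean dates between two dating schemes
#'
#' Ordinary least squares of scheme B's mean clade ages on scheme A's over
#' the shared clades (matched by taxon set), with optional clade
#' subsetting.
#'
#' @param result_a,result_b `"cf_dates"` tables.
#' @param subset_taxa Optional character vector: only clades whose taxa
#'   are all within this set are compared.
#' @return List with `slope`, `intercept`, `r_squared`, `n_clades`.
#' @export
compare_dating_schemes <- function(result_a, result_b, subset_taxa = NULL) {
  key_a <- result_a$taxa; key_b <- result_b$taxa
  shared <- intersect(key_a, key_b)
  if (!is.null(subset_taxa)) {
    keep <- vapply(strsplit(shared, ","), function(tx) all(tx %in% subset_taxa),
                   logical(1))
    shared <- shared[keep]
  }
  if (length(shared) < 3L) stop("need at least 3 shared clades")
  x <- result_a$mean[match(shared, key_a)]
  y <- result_b$mean[match(shared, key_b)]
  fit <- lm(y ~ x)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = r2, n_clades = length(shared))
}
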