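# Rooted-tree plumbing built on ape's "phylo" representation: Newick I/O
# with validation, clade bookkeeping, majority-rule consensus, chain
# comparison (bpcomp-style max_diff), and branch-length statistics.

#' Parse a Newick string into a validated rooted tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the pipeline relies on: unique tip labels, non-negative branch
#' lengths, and (when numeric internal labels are present) supports in
#' \[0, 1\] or percentages in \[0, 100\].
#'
#' @param text Newick string (single tree, terminated by `;`).
#' @return An object of class `"phylo"`; numeric internal node labels are
#'   kept in `node.label` as parsed.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text)) {
    stop("malformed Newick at offset ", nchar(text), ": missing terminal ';'")
  }
  # cheap structural pre-check with offset reporting
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick at offset ", i, ": unbalanced ')'")
    }
  }
  if (depth != 0L) stop("malformed Newick at offset ", nchar(text),
                        ": ", depth, " unclosed '('")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  validate_phylogram(tr)
  tr
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with enough digits to round-trip (10
#' significant digits); numeric supports are written as internal labels.
#'
#' @param tree A `"phylo"` object.
#' @param digits Significant digits for branch lengths.
#' @return Newick string.
#' @export
write_newick <- function(tree, digits = 10L) {
  ape::write.tree(tree, digits = digits)
}

#' Validate the phylogram invariants
#'
#' @param tree `"phylo"` object.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_phylogram <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths")
  }
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    sup <- sup[!is.na(sup)]
    if (length(sup) && any(sup < 0 | sup > 100)) {
      stop("node supports outside [0, 100]")
    }
  }
  invisible(TRUE)
}

# Descendant tip labels for every node, as a list indexed by node id.
.descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  out <- vector("list", nnode)
  # postorder over internal nodes
  ord <- rev(.preorder_nodes(tree))
  for (v in seq_len(ntip)) out[[v]] <- tree$tip.label[v]
  for (v in ord) {
    if (v > ntip) out[[v]] <- unlist(out[kids[[v]]], use.names = FALSE)
  }
  out
}

# Node ids in preorder (root first).
.preorder_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  stack <- root
  out <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  out
}

# Non-trivial clades (internal nodes other than the root) as sorted
# tip-label keys.
.clade_keys <- function(tree, include_root = FALSE) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  tips <- .descendant_tips(tree)
  ids <- (ntip + 1L):(ntip + tree$Nnode)
  if (!include_root) ids <- setdiff(ids, root)
  keys <- vapply(ids, function(v) paste(sort(tips[[v]]), collapse = "\r"),
                 character(1))
  names(keys) <- ids
  keys
}

.check_same_leaves <- function(trees) {
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop("trees have mismatched leaf sets (tree ", i, ")")
    }
  }
  ref
}

#' Clade frequencies across a tree sample
#'
#' Counts every non-trivial rooted clade (descendant tip set of an internal
#' non-root node) across the sample.
#'
#' @param trees List of `"phylo"` trees over the same leaf set.
#' @return Data frame with columns `clade` (tips joined by commas) and
#'   `freq` (fraction of trees containing the clade); attribute `n_trees`.
#' @export
clade_frequencies <- function(trees) {
  stopifnot(length(trees) >= 1L)
  .check_same_leaves(trees)
  tab <- table(unlist(lapply(trees, .clade_keys), use.names = FALSE))
  out <- data.frame(clade = gsub("\r", ",", names(tab)),
                    freq = as.numeric(tab) / length(trees),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq, out$clade), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_trees") <- length(trees)
  out
}

#' Majority-rule consensus of rooted trees
#'
#' Returns the tree containing exactly the clades whose sample frequency
#' strictly exceeds `min_freq` (plus the trivial clades), each annotated
#' with its frequency as the node label. With `min_freq >= 0.5` the
#' retained clades are pairwise compatible by construction.
#'
#' @param trees List of `"phylo"` trees over the same leaf set.
#' @param min_freq Retention threshold (strict), default 0.5.
#' @return A `"phylo"` tree; `node.label` holds clade frequencies with four
#'   decimals (empty for the root).
#' @export
majority_rule_consensus <- function(trees, min_freq = 0.5) {
  stopifnot(length(trees) >= 1L, min_freq >= 0.5, min_freq <= 1)
  leaves <- .check_same_leaves(trees)
  cf <- clade_frequencies(trees)
  keep <- cf[cf$freq > min_freq, , drop = FALSE]
  clades <- lapply(strsplit(keep$clade, ","), sort)
  freqs <- keep$freq
  # drop clade == all leaves if present (root is added explicitly)
  full <- vapply(clades, function(x) length(x) == length(leaves), logical(1))
  root_freq <- if (any(full)) freqs[full][1L] else 1
  clades <- clades[!full]; freqs <- freqs[!full]
  # build nested structure: order by decreasing size, attach to smallest
  # containing parent
  ord <- order(-lengths(clades))
  clades <- clades[ord]; freqs <- freqs[ord]
  n <- length(clades)
  newick_of <- function(members, children_idx, label) {
    # children_idx: indices of clades directly inside this one
    used <- unlist(clades[children_idx], use.names = FALSE)
    singles <- setdiff(members, used)
    parts <- c(
      vapply(children_idx, function(j) {
        inner <- which(vapply(seq_len(n), function(k) {
          k != j && length(clades[[k]]) < length(clades[[j]]) &&
            all(clades[[k]] %in% clades[[j]])
        }, logical(1)))
        # direct children of j: not contained in any other clade inside j
        direct <- inner[vapply(inner, function(k) {
          !any(vapply(inner, function(m) {
            m != k && all(clades[[k]] %in% clades[[m]])
          }, logical(1)))
        }, logical(1))]
        newick_of(clades[[j]], direct, sprintf("%.4f", freqs[j]))
      }, character(1)),
      singles
    )
    paste0("(", paste(parts, collapse = ","), ")", label)
  }
  top <- which(vapply(seq_len(n), function(k) {
    !any(vapply(seq_len(n), function(m) {
      m != k && length(clades[[k]]) < length(clades[[m]]) &&
        all(clades[[k]] %in% clades[[m]])
    }, logical(1)))
  }, logical(1)))
  txt <- paste0(newick_of(leaves, top, sprintf("%.4f", root_freq)), ";")
  tr <- ape::read.tree(text = txt)
  validate_phylogram(tr)
  tr
}

#' Maximum clade-frequency discrepancy between two tree samples
#'
#' The bpcomp-style convergence statistic: the maximum over all clades
#' observed in either sample of the absolute difference in clade frequency.
#'
#' @param sample_a,sample_b Non-empty lists of `"phylo"` trees over the
#'   same leaf set.
#' @return A number in \[0, 1\].
#' @export
max_clade_support_diff <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("empty tree sample")
  .check_same_leaves(c(sample_a, sample_b))
  fa <- clade_frequencies(sample_a)
  fb <- clade_frequencies(sample_b)
  keys <- union(fa$clade, fb$clade)
  if (!length(keys)) return(0)
  va <- setNames(rep(0, length(keys)), keys); va[fa$clade] <- fa$freq
  vb <- setNames(rep(0, length(keys)), keys); vb[fb$clade] <- fb$freq
  max(abs(va - vb))
}

#' Path lengths from an ancestral node to a set of tips
#'
#' Sums branch lengths from the most recent common ancestor of `ancestor`
#' down to each requested tip; branches above the MRCA are excluded.
#'
#' @param tree `"phylo"` with branch lengths.
#' @param ancestor Character vector of taxa whose MRCA defines the node.
#' @param tips Taxa to measure to; must descend from that MRCA. Defaults to
#'   all descendants of the MRCA.
#' @return List with `distances` (named numeric), `median`, `mean`, `sd`.
#' @export
node_to_tip_distances <- function(tree, ancestor, tips = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  missing_anc <- setdiff(ancestor, tree$tip.label)
  if (length(missing_anc)) {
    stop("ancestor taxa not in tree: ", paste(missing_anc, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  mrca <- if (length(ancestor) == 1L) {
    match(ancestor, tree$tip.label)
  } else {
    ape::getMRCA(tree, ancestor)
  }
  desc <- .descendant_tips(tree)[[mrca]]
  if (is.null(tips)) tips <- desc
  bad <- setdiff(tips, desc)
  if (length(bad)) {
    stop("tips not descendants of the MRCA: ", paste(bad, collapse = ", "))
  }
  # depth of every node below mrca
  depth <- rep(NA_real_, ntip + tree$Nnode)
  depth[mrca] <- 0
  ord <- .preorder_nodes(tree)
  edge_of_child <- integer(ntip + tree$Nnode)
  edge_of_child[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  for (v in ord) {
    e <- edge_of_child[v]
    if (v != mrca && e > 0L) {
      p <- tree$edge[e, 1L]
      if (!is.na(depth[p])) depth[v] <- depth[p] + tree$edge.length[e]
    }
  }
  d <- depth[match(tips, tree$tip.label)]
  names(d) <- tips
  list(distances = d, median = median(d), mean = mean(d),
       sd = if (length(d) > 1L) sd(d) else 0)
}

#' Node ages of an ultrametric tree
#'
#' @param tree Ultrametric `"phylo"` (a chronogram).
#' @param tol Relative tolerance for the ultrametricity check.
#' @return Numeric vector of ages (time before present) indexed by node id;
#'   tips are 0.
#' @export
node_ages <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ntip <- length(tree$tip.label)
  depth <- numeric(ntip + tree$Nnode)
  ord <- .preorder_nodes(tree)
  edge_of_child <- integer(ntip + tree$Nnode)
  edge_of_child[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  for (v in ord) {
    e <- edge_of_child[v]
    if (e > 0L) depth[v] <- depth[tree$edge[e, 1L]] + tree$edge.length[e]
  }
  h <- max(depth[seq_len(ntip)])
  if (h > 0 && max(abs(depth[seq_len(ntip)] - h)) > tol * max(h, 1)) {
    stop("tree is not ultrametric")
  }
  ages <- h - depth
  ages[seq_len(ntip)] <- 0
  ages
}

#' Validate the chronogram invariants
#'
#' Checks ultrametricity (tips at age 0) and that every parent is strictly
#' older than its children.
#'
#' @param tree `"phylo"` object.
#' @param tol Ultrametricity tolerance.
#' @return Invisibly the node-age vector.
#' @export
validate_chronogram <- function(tree, tol = 1e-6) {
  validate_phylogram(tree)
  ages <- node_ages(tree, tol = tol)
  bad <- ages[tree$edge[, 1L]] <= ages[tree$edge[, 2L]]
  # allow equality only within tolerance for zero-length terminal edges
  if (any(ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]] <= -tol)) {
    stop("parent not older than child")
  }
  invisible(ages)
}

# Build an ultrametric phylo from a topology skeleton and node ages.
# 'ages' indexed by node id (tips must be 0).
.tree_with_ages <- function(tree, ages) {
  tree$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  tree
}
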