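# Supermatrix assembly: per-gene alignments -> OTU-merged concatenated
# amino-acid matrix with partitions, missing-data accounting, gene
# jackknife resampling, and pairwise identity statistics.

# ---- gene alignments --------------------------------------------------

#' Construct a gene alignment
#'
#' @param id Gene identifier.
#' @param seqs Named character vector of aligned amino-acid sequences
#'   (equal lengths). Ambiguity codes and rare residues (B, Z, J, U, O) are
#'   normalized to the unknown character `?`; gaps stay `-`.
#' @return Object of class `"cf_gene"`: a character matrix (taxa x sites)
#'   with attribute `gene`.
#' @export
gene_alignment <- function(id, seqs) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[lens != lens[1L]][1L]
    stop("ragged alignment in gene '", id, "' at taxon '", bad, "'")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- trimws(names(seqs))
  m[m %in% .aa_unknown_chars] <- "?"
  ok <- m %in% c(aa_states(), "-", "?")
  if (!all(ok)) stop("gene '", id, "': unexpected characters ",
                     paste(unique(m[!ok]), collapse = " "))
  structure(m, gene = as.character(id), class = "cf_gene")
}

#' @export
print.cf_gene <- function(x, ...) {
  cat("<cf_gene> gene", attr(x, "gene"), ":", nrow(x), "taxa x",
      ncol(x), "sites\n")
  invisible(x)
}

.parse_fasta <- function(lines, path) {
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no FASTA records in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(starts), function(i) {
    paste(gsub("\\s", "", lines[(starts[i] + 1L):ends[i]]), collapse = "")
  }, character(1))
  names(seqs) <- trimws(sub("^>", "", lines[starts]))
  seqs
}

.parse_phylip <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("bad PHYLIP header in ", path)
  ntax <- hdr[1L]; nsites <- hdr[2L]
  toks <- unlist(strsplit(trimws(lines[-1L]), "\\s+"), use.names = FALSE)
  seqs <- character(ntax); nms <- character(ntax)
  i <- 1L
  for (t in seq_len(ntax)) {
    if (i > length(toks)) stop("truncated PHYLIP file ", path)
    nms[t] <- toks[i]; i <- i + 1L
    s <- ""
    while (nchar(s) < nsites) {
      if (i > length(toks)) {
        stop("ragged alignment in ", path, " at taxon '", nms[t], "'")
      }
      s <- paste0(s, toks[i]); i <- i + 1L
    }
    if (nchar(s) != nsites) {
      stop("ragged alignment in ", path, " at taxon '", nms[t], "'")
    }
    seqs[t] <- s
  }
  names(seqs) <- nms
  seqs
}

#' Read per-gene alignments from FASTA or relaxed PHYLIP files
#'
#' Format is auto-detected (`>` starts FASTA). The gene id is the file name
#' without extension. Relaxed PHYLIP is read sequentially: a name token
#' followed by sequence tokens until the header length is reached.
#'
#' @param paths Character vector of file paths.
#' @return List of [gene_alignment()] objects.
#' @export
read_gene_alignments <- function(paths) {
  lapply(paths, function(p) {
    lines <- readLines(p, warn = FALSE)
    if (!length(lines) || !any(nzchar(trimws(lines)))) stop("empty file ", p)
    first <- trimws(lines[which(nzchar(trimws(lines)))[1L]])
    seqs <- if (startsWith(first, ">")) .parse_fasta(lines, p)
            else .parse_phylip(lines, p)
    id <- sub("\\.[^.]*$", "", basename(p))
    tryCatch(gene_alignment(id, seqs), error = function(e) {
      stop(conditionMessage(e), " [file ", p, "]")
    })
  })
}

# ---- pairwise ML distance --------------------------------------------

#' Pairwise maximum-likelihood distance between two aligned sequences
#'
#' Maximizes the two-sequence likelihood over the evolutionary distance
#' under a reversible amino-acid model; the `+F` convention estimates
#' equilibrium frequencies from the sequence pair itself. Columns where
#' either sequence is a gap or unknown are ignored.
#'
#' @param seq_a,seq_b Character vectors of single residues (equal length),
#'   e.g. rows of a [gene_alignment()].
#' @param model Exchangeability scheme: `"wag"` (default), `"lg"`, or
#'   `"poisson"`.
#' @param max_dist Upper bound of the distance search interval.
#' @return Distance in expected substitutions per site.
#' @export
pairwise_ml_distance <- function(seq_a, seq_b, model = "wag", max_dist = 10) {
  stopifnot(length(seq_a) == length(seq_b))
  states <- aa_states()
  ia <- match(seq_a, states); ib <- match(seq_b, states)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) stop("no shared non-missing columns; distance undefined")
  ia <- ia[keep]; ib <- ib[keep]
  counts <- table(factor(ia, levels = 1:20), factor(ib, levels = 1:20))
  counts <- unclass(counts)
  # +F frequencies from the pair, with a small floor so observed states
  # never have zero equilibrium mass
  freq <- tabulate(c(ia, ib), nbins = 20L)
  pi <- (freq + 0.01) / sum(freq + 0.01)
  rho <- switch(model,
    poisson = uniform_exchangeabilities(),
    lg = .empirical_model("lg")$rho,
    wag = .empirical_model("wag")$rho,
    stop("unknown model '", model, "'"))
  eig <- .eigen_q(build_rate_matrix(rho, pi), pi)
  negll <- function(d) {
    P <- .prob_matrix(eig, d)
    -sum(counts * log(pmax(pi * P, 1e-300)))
  }
  if (all(ia == ib)) return(0)
  opt <- optimize(negll, c(1e-8, max_dist), tol = 1e-8)
  opt$minimum
}

# ---- OTU assembly -----------------------------------------------------

#' Pick the slowest-evolving representative of an OTU in one gene
#'
#' Among the candidate source taxa present in the gene, returns the one
#' with minimal mean pairwise ML distance to the background taxa — the
#' SCaFoS-style "slowest evolving sequence" rule. Ties break
#' lexicographically.
#'
#' @param gene A [gene_alignment()].
#' @param candidates Source taxa eligible to represent the OTU.
#' @param background Taxa to measure against (defaults to all non-candidate
#'   taxa in the gene).
#' @param model Exchangeability scheme for [pairwise_ml_distance()].
#' @param aggregate `"mean"` (default) or `"max"` over background distances.
#' @return The selected taxon name, or `NA_character_` if no candidate is
#'   present in the gene.
#' @export
choose_representative <- function(gene, candidates, background = NULL,
                                  model = "wag",
                                  aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  present <- intersect(candidates, rownames(gene))
  if (!length(present)) return(NA_character_)
  if (length(present) == 1L) return(present)
  if (is.null(background)) background <- setdiff(rownames(gene), candidates)
  background <- intersect(background, rownames(gene))
  if (!length(background)) return(sort(present)[1L])
  score <- vapply(sort(present), function(cand) {
    d <- vapply(background, function(b) {
      tryCatch(pairwise_ml_distance(gene[cand, ], gene[b, ], model = model),
               error = function(e) NA_real_)
    }, numeric(1))
    d <- d[!is.na(d)]
    if (!length(d)) return(Inf)
    if (aggregate == "mean") mean(d) else max(d)
  }, numeric(1))
  names(score)[which.min(score)]  # which.min takes the first (lexicographic) tie
}

#' Per-gene representative assignment for a chimeric OTU
#'
#' For each gene independently, chooses the source taxon whose sequence
#' will fill the OTU's row: the slowest-evolving source present
#' (`method = "slowest"`), or simply the first source present in the OTU's
#' ordered list (`method = "first"`). Genes with no source present are
#' marked missing.
#'
#' @param genes List of [gene_alignment()] objects.
#' @param sources Ordered character vector of source taxa for the OTU.
#' @param method `"slowest"` or `"first"`.
#' @param model Distance model for the slowest rule.
#' @return Data frame with columns `gene` and `source` (`NA` = missing).
#' @export
make_chimera <- function(genes, sources, method = c("slowest", "first"),
                         model = "wag") {
  method <- match.arg(method)
  rows <- lapply(genes, function(g) {
    src <- if (method == "first") {
      pres <- sources[sources %in% rownames(g)]
      if (length(pres)) pres[1L] else NA_character_
    } else {
      choose_representative(g, sources, model = model)
    }
    data.frame(gene = attr(g, "gene"), source = src,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# number of OTUs with no representative for each gene
.gene_missing_counts <- function(genes, otus) {
  vapply(genes, function(g) {
    sum(vapply(otus, function(src) !any(src %in% rownames(g)), logical(1)))
  }, integer(1))
}

#' Filter genes by number of missing OTUs
#'
#' @param genes List of [gene_alignment()] objects.
#' @param otus Named list: OTU name -> character vector of source taxa.
#' @param max_missing Retain genes with at most this many OTUs absent
#'   (default 15, inclusive).
#' @return The retained subset of `genes`.
#' @export
filter_by_missing <- function(genes, otus, max_missing = 15L) {
  keep <- .gene_missing_counts(genes, otus) <= max_missing
  genes[keep]
}

#' Concatenate gene alignments into a supermatrix
#'
#' Builds the OTU x site character matrix with gene partitions recorded as
#' 0-based half-open column intervals, filling each OTU row gene-by-gene
#' from its source taxa (chimera construction). Cells with no
#' representative are `?`.
#'
#' @param genes List of [gene_alignment()] objects with unique gene ids.
#' @param otus Named list OTU -> source taxa; `NULL` treats every taxon
#'   observed in any gene as its own OTU.
#' @param method Representative rule passed to [make_chimera()]; the
#'   default `"first"` is exact when OTUs have a single source and fast;
#'   use `"slowest"` for the SCaFoS-style rule.
#' @param count_gaps_as_missing Whether `-` counts towards the missing-data
#'   percentage along with `?` (default `TRUE`).
#' @return Object of class `"cf_supermatrix"`: list with `matrix`,
#'   `partitions` (data frame `gene`, `start`, `end`), and `stats`
#'   (`n_genes`, `n_otus`, `n_sites`, `pct_missing`).
#' @export
concatenate <- function(genes, otus = NULL, method = "first",
                        count_gaps_as_missing = TRUE) {
  stopifnot(length(genes) >= 1L)
  ids <- vapply(genes, attr, character(1), "gene")
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(otus)) {
    taxa <- sort(unique(unlist(lapply(genes, rownames))))
    otus <- setNames(as.list(taxa), taxa)
  }
  lens <- vapply(genes, ncol, integer(1))
  ends <- cumsum(lens)
  starts <- c(0L, head(ends, -1L))
  n_sites <- sum(lens)
  m <- matrix("?", nrow = length(otus), ncol = n_sites,
              dimnames = list(names(otus), NULL))
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    cols <- (starts[gi] + 1L):ends[gi]
    for (oi in seq_along(otus)) {
      asg <- make_chimera(list(g), otus[[oi]], method = method)
      if (!is.na(asg$source[1L])) m[oi, cols] <- g[asg$source[1L], ]
    }
  }
  miss_chars <- if (count_gaps_as_missing) c("?", "-") else "?"
  pct_missing <- 100 * sum(m %in% miss_chars) / length(m)
  structure(list(
    matrix = m,
    partitions = data.frame(gene = ids, start = starts, end = ends,
                            stringsAsFactors = FALSE),
    stats = list(n_genes = length(genes), n_otus = length(otus),
                 n_sites = n_sites, pct_missing = pct_missing)
  ), class = "cf_supermatrix")
}

#' @export
print.cf_supermatrix <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<cf_supermatrix> %d OTUs x %d sites (%d genes, %.1f%% missing)\n",
              s$n_otus, s$n_sites, s$n_genes, s$pct_missing))
  invisible(x)
}

#' Extract one gene's alignment back out of a supermatrix
#'
#' @param sm A [concatenate()] result.
#' @param gene Gene id.
#' @return Character matrix (OTU x sites) for that partition.
#' @export
extract_partition <- function(sm, gene) {
  p <- sm$partitions[sm$partitions$gene == gene, , drop = FALSE]
  if (!nrow(p)) stop("no partition named '", gene, "'")
  sm$matrix[, (p$start[1L] + 1L):p$end[1L], drop = FALSE]
}

# ---- jackknife --------------------------------------------------------

#' Draw a gene-jackknife resampling scheme
#'
#' Each replicate draws `k` distinct genes uniformly without replacement,
#' independently across replicates; reproducible under a fixed seed.
#'
#' @param gene_ids Character vector of gene ids (or list of gene
#'   alignments).
#' @param k Genes per replicate (default 130).
#' @param replicates Number of replicates (default 100).
#' @param seed Integer RNG seed.
#' @return Object of class `"cf_jackknife"`: list with `replicates` (list
#'   of id vectors), `k`, `seed`.
#' @export
gene_jackknife <- function(gene_ids, k = 130L, replicates = 100L, seed = 1L) {
  if (is.list(gene_ids)) {
    gene_ids <- vapply(gene_ids, attr, character(1), "gene")
  }
  n <- length(gene_ids)
  if (k > n) stop("k = ", k, " exceeds number of genes (", n, ")")
  reps <- .with_seed(seed, {
    lapply(seq_len(replicates), function(i) sample(gene_ids, k))
  })
  structure(list(replicates = reps, k = k, seed = seed),
            class = "cf_jackknife")
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gene-jackknife support from replicate consensus trees
#'
#' @param trees List of replicate consensus trees (`"phylo"`, same leaves).
#' @return Data frame `clade`, `js` (percent of replicate consensus trees
#'   containing the clade); attribute `n_trees`.
#' @export
jackknife_support <- function(trees) {
  cf <- clade_frequencies(trees)
  out <- data.frame(clade = cf$clade, js = 100 * cf$freq,
                    stringsAsFactors = FALSE)
  attr(out, "n_trees") <- attr(cf, "n_trees")
  out
}

# ---- identity ---------------------------------------------------------

#' Percent amino-acid identity between two supermatrix rows
#'
#' Computed over columns where both OTUs carry a residue; gaps and unknowns
#' are excluded from numerator and denominator.
#'
#' @param sm A [concatenate()] result (or plain character matrix).
#' @param otu_a,otu_b Row names.
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(sm, otu_a, otu_b) {
  m <- if (inherits(sm, "cf_supermatrix")) sm$matrix else sm
  a <- m[otu_a, ]; b <- m[otu_b, ]
  ok <- a %in% aa_states() & b %in% aa_states()
  if (!any(ok)) stop("no comparable columns between '", otu_a, "' and '",
                     otu_b, "'")
  100 * sum(a[ok] == b[ok]) / sum(ok)
}
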