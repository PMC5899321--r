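# Synthetic benchmark generation: conditioned birth-death chronograms,
# lineage rates under the clock models, amino-acid alignments with gene
# blocks and block-structured missing data, and bundled presets with
# ground truth attached.

#' Simulate a conditioned birth-death chronogram
#'
#' Draws the `n_tips - 2` non-root node ages i.i.d. from the birth-death
#' speciation-age distribution conditioned on the root age and builds the
#' ranked topology by uniform lineage splitting; the result is ultrametric
#' with the root at `root_age`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param lambda,mu Birth and death rates (`lambda > mu >= 0`).
#' @param root_age Root age (Mya).
#' @param tip_labels Optional tip names (default `t1..tn`).
#' @return An ultrametric `"phylo"`.
#' @export
simulate_chronogram <- function(n_tips, lambda = 0.1, mu = 0.025,
                                root_age = 540, tip_labels = NULL) {
  stopifnot(n_tips >= 2L, lambda > mu, mu >= 0, root_age > 0)
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n_tips))
  stopifnot(length(tip_labels) == n_tips)
  nnode <- 2L * n_tips - 1L
  root <- n_tips + 1L
  ages <- numeric(nnode)
  ages[root] <- root_age
  if (n_tips > 2L) {
    u <- runif(n_tips - 2L)
    ages[(root + 1L):nnode] <- sort(.bd_quantile(u, lambda, mu, root_age),
                                    decreasing = TRUE)
  }
  # ranked construction: split a uniformly chosen active lineage at each
  # successive (descending) internal age
  edge <- matrix(0L, nrow = nnode - 1L, ncol = 2L)
  elen <- numeric(nnode - 1L)
  ei <- 0L
  active_parent <- c(root, root)   # lineages awaiting an endpoint
  if (n_tips > 2L) {
    for (k in seq_len(n_tips - 2L)) {
      v <- root + k
      i <- sample.int(length(active_parent), 1L)
      ei <- ei + 1L
      edge[ei, ] <- c(active_parent[i], v)
      elen[ei] <- ages[active_parent[i]] - ages[v]
      active_parent <- c(active_parent[-i], v, v)
    }
  }
  tip_order <- sample.int(n_tips)
  for (j in seq_along(active_parent)) {
    ei <- ei + 1L
    edge[ei, ] <- c(active_parent[j], tip_order[j])
    elen[ei] <- ages[active_parent[j]]
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = tip_labels, Nnode = n_tips - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  validate_chronogram(tr)
  tr
}

#' Simulate lineage rates under a clock model
#'
#' LN: recursive log-normal sampling down the tree with the mean
#' correction that keeps `E[r_child] = r_parent`; UGAM: i.i.d. gamma
#' branch rates; CL: constant. An optional elevation preset multiplies the
#' base rate inside a designated subtree (emulating lineage-specific rate
#' acceleration).
#'
#' @param tree Ultrametric `"phylo"`.
#' @param clock A [clock_model()].
#' @param elevate Optional `list(taxa = ..., factor = ...)`: all nodes in
#'   the subtree spanned by `taxa` get their (expected) rate multiplied.
#' @return Object of class `"cf_rates"`: `node_rates` (per node),
#'   `branch_rates` (per child node), `clock`.
#' @export
simulate_rates <- function(tree, clock, elevate = NULL) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  ages <- node_ages(tree)
  mult <- rep(1, nnode)
  if (!is.null(elevate)) {
    m <- if (length(elevate$taxa) == 1L) match(elevate$taxa, tree$tip.label)
         else ape::getMRCA(tree, elevate$taxa)
    sub <- logical(nnode); sub[m] <- TRUE
    for (v in .preorder_nodes(tree)) {
      if (!sub[v]) {
        p <- tree$edge[match(v, tree$edge[, 2L]), 1L]
        if (!is.na(p) && sub[p]) sub[v] <- TRUE
      }
    }
    mult[sub] <- elevate$factor
  }
  node_rates <- rep(clock$mu_r, nnode)
  branch_rates <- rep(clock$mu_r, nnode)
  if (clock$kind == "ln") {
    node_rates[root] <- clock$mu_r *
      exp(rnorm(1, -clock$root_spread^2 / 2, clock$root_spread))
    for (v in .preorder_nodes(tree)) {
      if (v == root) next
      p <- tree$edge[match(v, tree$edge[, 2L]), 1L]
      dt <- ages[p] - ages[v]
      s2 <- clock$sigma2
      node_rates[v] <- node_rates[p] *
        exp(rnorm(1, -s2 * dt / 2, sqrt(s2 * dt)))
    }
    node_rates <- node_rates * mult
    ch <- tree$edge[, 2L]
    branch_rates[ch] <- (node_rates[tree$edge[, 1L]] + node_rates[ch]) / 2
  } else if (clock$kind == "ugam") {
    ch <- tree$edge[, 2L]
    shape <- if (clock$nu > 0) 1 / clock$nu else Inf
    br <- if (is.finite(shape)) {
      rgamma(length(ch), shape = shape, scale = clock$nu * clock$mu_r)
    } else rep(clock$mu_r, length(ch))
    branch_rates[ch] <- br * mult[ch]
    node_rates <- branch_rates
  } else {
    node_rates <- node_rates * mult
    ch <- tree$edge[, 2L]
    branch_rates[ch] <- (node_rates[tree$edge[, 1L]] + node_rates[ch]) / 2
  }
  structure(list(node_rates = node_rates, branch_rates = branch_rates,
                 clock = clock),
            class = "cf_rates")
}

# substitution branch lengths implied by a chronogram + rates
.rates_branch_lengths <- function(tree, rates) {
  ages <- node_ages(tree)
  ch <- tree$edge[, 2L]
  (ages[tree$edge[, 1L]] - ages[ch]) * rates$branch_rates[ch]
}

#' Simulate a gene-partitioned amino-acid alignment on a chronogram
#'
#' Branch substitution lengths integrate the lineage rates over each
#' branch (trapezoid of endpoint rates times duration). Sites evolve
#' root-to-tips under the model's profile(s) with discrete-gamma site
#' rates; missingness is applied as whole taxon-by-gene blocks until the
#' target global fraction is reached (no taxon is blanked entirely).
#'
#' @param tree Ultrametric `"phylo"`.
#' @param rates A [simulate_rates()] result.
#' @param model An [aa_model()]; CAT models assign each site a profile
#'   (uniformly if `site_comp` is `NULL`).
#' @param gene_lengths Integer vector of per-gene site counts.
#' @param missing_fraction Target global missing fraction in \[0, 0.9\].
#' @return List with `genes` (list of [gene_alignment()]), `supermatrix`
#'   (via [concatenate()]), `site_comp`, `site_rate_cat`.
#' @export
simulate_alignment <- function(tree, rates, model, gene_lengths,
                               missing_fraction = 0) {
  stopifnot(missing_fraction >= 0, missing_fraction <= 0.9)
  nsites <- sum(gene_lengths)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  mc <- .model_components(model, nsites)
  if (model$is_cat && is.null(model$site_comp) && length(mc$comps) > 1L) {
    mc$site_comp <- sample.int(length(mc$comps), nsites, replace = TRUE)
  }
  g <- discrete_gamma_rates(model$alpha, model$ncat)
  site_cat <- sample.int(model$ncat, nsites, replace = TRUE)
  bl <- .rates_branch_lengths(tree, rates)
  states <- matrix(0L, nnode, nsites)
  for (ci in seq_along(mc$comps)) {
    idx <- which(mc$site_comp == ci)
    if (length(idx)) {
      states[root, idx] <- sample.int(20L, length(idx), replace = TRUE,
                                      prob = mc$comps[[ci]]$pi)
    }
  }
  ord <- .preorder_nodes(tree)
  for (v in ord) {
    if (v == root) next
    e <- match(v, tree$edge[, 2L])
    p <- tree$edge[e, 1L]
    for (ci in seq_along(mc$comps)) {
      for (k in seq_len(model$ncat)) {
        idx <- which(mc$site_comp == ci & site_cat == k)
        if (!length(idx)) next
        P <- .prob_matrix(mc$comps[[ci]], bl[e] * g$rates[k])
        P <- pmax(P, 0); P <- P / rowSums(P)
        for (a in unique(states[p, idx])) {
          ii <- idx[states[p, idx] == a]
          states[v, ii] <- sample.int(20L, length(ii), replace = TRUE,
                                      prob = P[a, ])
        }
      }
    }
  }
  chars <- matrix(aa_states()[states[seq_len(ntip), , drop = FALSE]],
                  nrow = ntip, dimnames = list(tree$tip.label, NULL))
  # block-structured missingness
  ngene <- length(gene_lengths)
  ends <- cumsum(gene_lengths); starts <- c(0L, head(ends, -1L)) + 1L
  if (missing_fraction > 0) {
    total <- ntip * nsites
    blocked <- matrix(FALSE, ntip, ngene)
    miss_cells <- 0L
    # random (taxon, gene) order; never blank a taxon's last gene
    cand <- expand.grid(taxon = seq_len(ntip), gene = seq_len(ngene))
    cand <- cand[sample.int(nrow(cand)), ]
    for (r in seq_len(nrow(cand))) {
      if (miss_cells >= missing_fraction * total) break
      tx <- cand$taxon[r]; gn <- cand$gene[r]
      if (sum(blocked[tx, ]) >= ngene - 1L) next
      blocked[tx, gn] <- TRUE
      chars[tx, starts[gn]:ends[gn]] <- "?"
      miss_cells <- miss_cells + gene_lengths[gn]
    }
  }
  genes <- lapply(seq_len(ngene), function(gi) {
    seqs <- apply(chars[, starts[gi]:ends[gi], drop = FALSE], 1L, paste,
                  collapse = "")
    gene_alignment(sprintf("gene%03d", gi), seqs)
  })
  list(genes = genes, supermatrix = concatenate(genes),
       site_comp = mc$site_comp, site_rate_cat = site_cat)
}

# ---- scaffold topology for the study-shaped preset --------------------

# A synthetic stand-in deuterostome topology (63 tips) carrying the genus
# names the packaged calibration fixture anchors to. Built in code; not
# the study's own consensus tree.
.deutero63_newick <- function() {
  echinoderms <- paste0("(Antedon_mediterranea,((Patiria_miniata,",
    "Ophionotus_victoriae),(Apostichopus_japonicus,(Eucidaris_tribuloides,",
    "(Strongylocentrotus_purpuratus,Sphaerechinus_granularis)))))")
  xenambulacraria <- paste0("(Xenoturbella_bocki,((Saccoglossus_kowalevskii,",
    "Ptychodera_flava),", echinoderms, "))")
  stolidobranchia <- paste0("((Bostrichobranchus_pilularis,",
    "(Molgula_occidentalis,(Molgula_manhattensis,Molgula_tectiformis))),",
    "(Halocynthia_roretzi,(Styela_plicata,(Botryllus_schlosseri,",
    "(Polyandrocarpa_anguinea,Dendrodoa_grossularia)))))")
  aplousobranchia <- "(Clavelina_lepadiformis,(Diplosoma_listerianum,Cystodytes_dellechiajei))"
  thaliacea <- "(Salpa_fusiformis,Doliolum_nationalis)"
  tunicata <- paste0("(Oikopleura_dioica,(", stolidobranchia, ",(",
    thaliacea, ",(Phallusia_mammillata,((Ciona_robusta,Ciona_savignyi),",
    aplousobranchia, ")))))")
  teleostei <- paste0("((Danio_rerio,(Esox_lucius,Salmo_salar)),",
    "(Oryzias_latipes,(Oreochromis_niloticus,(Gasterosteus_aculeatus,",
    "Takifugu_rubripes))))")
  actinopterygii <- paste0("(Polypterus_senegalus,(Lepisosteus_oculatus,",
    teleostei, "))")
  amphibia <- paste0("(Ambystoma_mexicanum,((Xenopus_tropicalis,",
    "Xenopus_laevis),Rana_chensinensis))")
  mammalia <- paste0("(Ornithorhynchus_anatinus,(Monodelphis_domestica,",
    "((Homo_sapiens,Mus_musculus),(Canis_familiaris,(Bos_taurus,",
    "Loxodonta_africana)))))")
  sauropsida <- paste0("((Sphenodon_punctatus,Anolis_carolinensis),",
    "((Phrynops_hilarii,Chrysemys_picta),((Crocodylus_porosus,",
    "Alligator_mississippiensis),(Gallus_gallus,Taeniopygia_guttata))))")
  tetrapoda <- paste0("(", amphibia, ",(", mammalia, ",", sauropsida, "))")
  osteichthyes <- paste0("(", actinopterygii, ",(Latimeria_chalumnae,",
    tetrapoda, "))")
  chondrichthyes <- "(Callorhinchus_milii,(Leucoraja_erinacea,Scyliorhinus_canicula))"
  vertebrata <- paste0("((Eptatretus_burgeri,Petromyzon_marinus),(",
    chondrichthyes, ",", osteichthyes, "))")
  chordata <- paste0("(Branchiostoma_lanceolatum,(", tunicata, ",",
    vertebrata, "))")
  paste0("(", xenambulacraria, ",", chordata, ");")
}

# reference ages (Mya) pinned at the calibration-relevant nodes of the
# scaffold; remaining internal ages are interpolated with seeded jitter
.deutero63_pinned_ages <- function() {
  list(
    list(taxa = c("Xenoturbella_bocki", "Homo_sapiens"), age = 560),  # root
    list(taxa = c("Homo_sapiens", "Branchiostoma_lanceolatum"), age = 550), # Chordata
    list(taxa = c("Homo_sapiens", "Ciona_robusta"), age = 535),       # Olfactores
    list(taxa = c("Homo_sapiens", "Petromyzon_marinus"), age = 520),  # Vertebrata
    list(taxa = c("Homo_sapiens", "Callorhinchus_milii"), age = 440), # Gnathostomata
    list(taxa = c("Homo_sapiens", "Danio_rerio"), age = 419),         # Osteichthyes
    list(taxa = c("Homo_sapiens", "Xenopus_tropicalis"), age = 340),  # Tetrapoda
    list(taxa = c("Homo_sapiens", "Gallus_gallus"), age = 320),       # Amniota
    list(taxa = c("Gallus_gallus", "Anolis_carolinensis"), age = 278),# Diapsida
    list(taxa = c("Xenopus_tropicalis", "Rana_chensinensis"), age = 250), # Batrachia
    list(taxa = c("Danio_rerio", "Oryzias_latipes"), age = 158),      # Clupeocephala
    list(taxa = c("Homo_sapiens", "Ornithorhynchus_anatinus"), age = 177), # Mammalia
    list(taxa = c("Homo_sapiens", "Monodelphis_domestica"), age = 148),    # Theria
    list(taxa = c("Strongylocentrotus_purpuratus", "Sphaerechinus_granularis"),
         age = 120),
    list(taxa = c("Strongylocentrotus_purpuratus", "Eucidaris_tribuloides"),
         age = 260)  # Echinoidea
  )
}

#' Synthetic study-shaped chronogram (63 deuterostome-named tips)
#'
#' Builds the packaged 63-taxon scaffold topology (a synthetic stand-in
#' whose tips carry the genus names the calibration fixture anchors to),
#' pins the calibration-relevant nodes at reference ages compatible with
#' the packaged constraints, and interpolates the remaining node ages with
#' seeded jitter.
#'
#' @return An ultrametric `"phylo"` with 63 tips.
#' @export
deutero63_chronogram <- function() {
  topo <- ape::read.tree(text = .deutero63_newick())
  ntip <- length(topo$tip.label)
  nnode <- ntip + topo$Nnode
  root <- ntip + 1L
  pinned <- rep(NA_real_, nnode)
  for (p in .deutero63_pinned_ages()) {
    pinned[ape::getMRCA(topo, p$taxa)] <- p$age
  }
  tips <- .descendant_tips(topo)
  # max pinned age strictly inside each subtree (excluding the node itself)
  ages <- numeric(nnode)
  parent_of <- integer(nnode); parent_of[topo$edge[, 2L]] <- topo$edge[, 1L]
  max_pinned_below <- function(v) {
    kids <- topo$edge[topo$edge[, 1L] == v, 2L]
    m <- 0
    for (k in kids) {
      if (k > ntip) {
        m <- max(m, if (!is.na(pinned[k])) pinned[k] else max_pinned_below(k))
      }
    }
    m
  }
  for (v in .preorder_nodes(topo)) {
    if (v <= ntip) next
    if (!is.na(pinned[v])) {
      ages[v] <- pinned[v]
    } else if (v == root) {
      ages[v] <- max_pinned_below(v) * 1.05
    } else {
      lo <- max_pinned_below(v)
      hi <- ages[parent_of[v]]
      ages[v] <- lo + (hi - lo) * runif(1, 0.3, 0.8)
    }
  }
  tr <- .tree_with_ages(topo, ages)
  validate_chronogram(tr)
  tr
}

# ---- benchmark presets ------------------------------------------------

#' Generate a fully specified synthetic benchmark
#'
#' Bundles a chronogram, true lineage rates, a simulated gene-partitioned
#' alignment with block missing data, and a calibration set, with all
#' ground truth attached; regeneration from the same `(preset, seed)` is
#' bit-identical.
#'
#' Presets: `"tiny"` — 8 taxa, 5 genes x 200 sites, LN clock, 2
#' calibrations derived from the true ages; `"deutero63"` — the
#' 63-taxon scaffold with 20 genes x 100 sites, the packaged
#' 13-constraint calibration fixture, and a 6.25-fold rate elevation in
#' the tunicate-named subtree.
#'
#' @param preset `"tiny"` or `"deutero63"`.
#' @param seed Integer seed.
#' @return Object of class `"cf_benchmark"`: `tree`, `rates`, `clock`,
#'   `model`, `genes`, `supermatrix`, `calibrations`, `root_prior`,
#'   `preset`, `seed`.
#' @export
make_benchmark <- function(preset = c("tiny", "deutero63"), seed = 1L) {
  preset <- match.arg(preset)
  .with_seed(seed, {
    if (preset == "tiny") {
      root_age <- 540 * runif(1, 0.8, 1.2)
      tree <- simulate_chronogram(8L, lambda = 0.02, mu = 0.005,
                                  root_age = root_age)
      clock <- clock_model("ln", mu_r = 2e-3, sigma2 = 1e-3)
      rates <- simulate_rates(tree, clock)
      model <- aa_model("poisson", alpha = 0.8, ncat = 4L)
      sim <- simulate_alignment(tree, rates, model,
                                gene_lengths = rep(200L, 5L),
                                missing_fraction = 0.2)
      # calibrations from the true ages of the root and one inner node
      ages <- node_ages(tree)
      ntip <- length(tree$tip.label)
      root <- ntip + 1L
      tips <- .descendant_tips(tree)
      inner <- setdiff((ntip + 1L):(ntip + tree$Nnode), root)
      # deepest non-root internal node
      pick <- inner[which.max(ages[inner])]
      cals <- list(
        calibration("root_clade", tips[[root]],
                    min_age = 0.9 * ages[root], max_age = 1.1 * ages[root]),
        calibration("inner_clade", tips[[pick]],
                    min_age = 0.9 * ages[pick], max_age = 1.1 * ages[pick]))
    } else {
      tree <- deutero63_chronogram()
      clock <- clock_model("ln", mu_r = 4e-4, sigma2 = 1e-3)
      rates <- simulate_rates(tree, clock,
                              elevate = list(taxa = c("Oikopleura_dioica",
                                                      "Styela_plicata"),
                                             factor = 6.25))
      profiles <- lapply(1:4, function(i) .rdirichlet(rep(0.5, 20)))
      model <- aa_model("cat-f81", alpha = 0.8, ncat = 4L,
                        profiles = profiles)
      sim <- simulate_alignment(tree, rates, model,
                                gene_lengths = rep(100L, 20L),
                                missing_fraction = 0.2)
      cals <- read_calibrations()
    }
    structure(list(tree = tree, rates = rates, clock = clock, model = model,
                   genes = sim$genes, supermatrix = sim$supermatrix,
                   site_comp = sim$site_comp,
                   calibrations = cals, root_prior = root_prior(540),
                   preset = preset, seed = seed),
              class = "cf_benchmark")
  })
}

#' @export
print.cf_benchmark <- function(x, ...) {
  cat(sprintf("<cf_benchmark> preset '%s' (seed %d): %d taxa, %d genes, %d sites\n",
              x$preset, x$seed, length(x$tree$tip.label),
              x$supermatrix$stats$n_genes, x$supermatrix$stats$n_sites))
  invisible(x)
}
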