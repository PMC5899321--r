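# Alignment reading, OTU merging, concatenation, jackknife, identity.

test_that("gene alignments read from FASTA and relaxed PHYLIP, normalized", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">tx1", "ARNDARNDCC", ">tx2 ", "ARNDARNDCB",
               ">tx3", "AR-DARNDC?"), fa)
  g <- read_gene_alignments(fa)[[1]]
  expect_equal(dim(g), c(3L, 10L))
  expect_equal(attr(g, "gene"), sub("\\.fasta$", "", basename(fa)))
  expect_equal(unname(g["tx2", 10]), "?")   # B normalized to unknown
  expect_equal(unname(g["tx3", 3]), "-")

  ph <- tempfile(fileext = ".phy")
  writeLines(c("4 12", "alpha ARNDCQEGHILK", "beta  ARNDCQEGHILK",
               "gamma ARND CQEG HILK", "delta ARNDCQEGHIL M"), ph)
  g2 <- read_gene_alignments(ph)[[1]]
  expect_equal(dim(g2), c(4L, 12L))
  expect_equal(rownames(g2), c("alpha", "beta", "gamma", "delta"))

  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ARND", ">b", "ARNDC"), ragged)
  expect_error(read_gene_alignments(ragged), "ragged.*b")
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_gene_alignments(empty), "empty")
})

test_that("pairwise ML distance recovers simulated distances (grid oracle)", {
  set.seed(3)
  wag <- chronoforge:::.empirical_model("wag")
  pair <- simulate_pair(0.3, wag$rho, wag$freqs, 1e5)
  d <- pairwise_ml_distance(pair$a, pair$b, model = "wag")
  # independent fine-grid likelihood maximization
  states <- aa_states()
  ia <- match(pair$a, states); ib <- match(pair$b, states)
  counts <- unclass(table(factor(ia, levels = 1:20), factor(ib, levels = 1:20)))
  freq <- tabulate(c(ia, ib), 20); piF <- (freq + 0.01) / sum(freq + 0.01)
  Q <- build_rate_matrix(wag$rho, piF)
  e <- eigen(Q); Vi <- solve(e$vectors)
  ll <- function(x) {
    P <- Re(e$vectors %*% diag(exp(e$values * x)) %*% Vi)
    sum(counts * log(pmax(piF * P, 1e-300)))
  }
  grid <- seq(0.2, 0.45, by = 5e-4)
  d_grid <- grid[which.max(vapply(grid, ll, numeric(1)))]
  expect_lt(abs(d - d_grid), 0.01)
  expect_lt(abs(d - 0.3), 0.02)
})

test_that("ML distance is zero for identical pairs and symmetric", {
  set.seed(4)
  s <- sample(aa_states(), 200, replace = TRUE)
  expect_equal(pairwise_ml_distance(s, s), 0)
  for (i in 1:10) {
    a <- sample(aa_states(), 300, replace = TRUE)
    b <- sample(aa_states(), 300, replace = TRUE)
    expect_equal(pairwise_ml_distance(a, b), pairwise_ml_distance(b, a),
                 tolerance = 1e-6)
  }
  expect_error(pairwise_ml_distance(c("-", "?"), c("A", "-")),
               "no shared")
})

test_that("representative choice follows the slowest-evolving rule", {
  set.seed(9)
  taxa <- c("bgA", "bgB", "bgC")
  base <- sample(aa_states(), 300, replace = TRUE)
  mut <- function(s, n) {
    i <- sample(seq_along(s), n)
    s[i] <- sample(aa_states(), n, replace = TRUE)
    s
  }
  seqs <- c(
    candA = paste(mut(base, 15), collapse = ""),
    candB = paste(mut(mut(base, 15), 60), collapse = ""),
    setNames(vapply(1:3, function(i) paste(mut(base, 10), collapse = ""),
                    character(1)), taxa))
  g <- gene_alignment("g1", seqs)
  expect_equal(choose_representative(g, "candA"), "candA")
  expect_equal(choose_representative(g, c("candA", "candB"), taxa), "candA")
  # identical candidates: lexicographically first
  seqs2 <- c(zed = seqs[["candA"]], abe = seqs[["candA"]],
             seqs[taxa])
  g2 <- gene_alignment("g2", seqs2)
  expect_equal(choose_representative(g2, c("zed", "abe"), taxa), "abe")
  expect_true(is.na(choose_representative(g, "absent")))
})

test_that("chimera assembly fills genes from available sources", {
  g1 <- random_gene("g1", c("X", "o1", "o2"), 20)
  g2 <- random_gene("g2", c("Y", "o1", "o2"), 20)
  asg <- make_chimera(list(g1, g2), c("X", "Y"), method = "first")
  expect_equal(asg$source, c("X", "Y"))
  asg2 <- make_chimera(list(g1), c("Y"), method = "first")
  expect_true(is.na(asg2$source))
  # both present: agrees with choose_representative
  g3 <- random_gene("g3", c("X", "Y", "o1", "o2"), 60)
  asg3 <- make_chimera(list(g3), c("X", "Y"), method = "slowest")
  expect_equal(asg3$source,
               choose_representative(g3, c("X", "Y"), c("o1", "o2")))
})

test_that("missing-OTU filter uses an inclusive boundary", {
  otus <- setNames(lapply(paste0("t", 1:63), identity), paste0("t", 1:63))
  g_complete <- random_gene("gc", paste0("t", 1:63), 5)
  g_m15 <- random_gene("g15", paste0("t", 1:48), 5)   # 15 missing
  g_m16 <- random_gene("g16", paste0("t", 1:47), 5)   # 16 missing
  kept <- filter_by_missing(list(g_complete, g_m15, g_m16), otus)
  ids <- vapply(kept, attr, character(1), "gene")
  expect_setequal(ids, c("gc", "g15"))
})

test_that("concatenation records partitions and missing-data stats", {
  g1 <- gene_alignment("g1", c(u = "ARN", v = "ARD"))
  g2 <- gene_alignment("g2", c(u = "CCCC", v = "CCCA"))
  sm <- concatenate(list(g1, g2))
  expect_equal(sm$stats$n_sites, 7L)
  expect_equal(sm$partitions$start, c(0L, 3L))
  expect_equal(sm$partitions$end, c(3L, 7L))
  expect_equal(sm$stats$pct_missing, 0)
  expect_equal(extract_partition(sm, "g1"), unclass(g1)[rownames(sm$matrix), ],
               ignore_attr = TRUE)

  # gene2 absent from one OTU: 4 of 14 cells missing
  g2b <- gene_alignment("g2", c(u = "CCCC"))
  sm2 <- concatenate(list(g1, g2b))
  expect_equal(sm2$stats$pct_missing, 100 * 4 / 14)

  # invariance under gene reordering
  sm3 <- concatenate(list(g2b, g1))
  expect_equal(sm3$stats$pct_missing, sm2$stats$pct_missing)

  expect_error(concatenate(list(g1, g1)), "duplicate")
})

test_that("gene jackknife draws reproducible distinct subsets", {
  ids <- sprintf("g%03d", 1:258)
  js <- gene_jackknife(ids, k = 130, replicates = 100, seed = 5)
  expect_length(js$replicates, 100L)
  expect_true(all(vapply(js$replicates, function(r) {
    length(r) == 130L && !anyDuplicated(r) && all(r %in% ids)
  }, logical(1))))
  js2 <- gene_jackknife(ids, k = 130, replicates = 100, seed = 5)
  expect_identical(js$replicates, js2$replicates)
  js3 <- gene_jackknife(ids, k = 130, replicates = 100, seed = 6)
  expect_false(identical(js$replicates, js3$replicates))
  # k = n: every replicate is the full set
  js4 <- gene_jackknife(ids[1:10], k = 10, replicates = 5, seed = 1)
  expect_true(all(vapply(js4$replicates, function(r) setequal(r, ids[1:10]),
                         logical(1))))
  expect_error(gene_jackknife(ids[1:10], k = 11), "exceeds")
})

test_that("jackknife support counts replicate consensus trees", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  trees <- c(replicate(42, t1, simplify = FALSE),
             replicate(58, t2, simplify = FALSE))
  js <- jackknife_support(trees)
  expect_equal(js$js[js$clade == "A,B"], 42)
  expect_equal(js$js[js$clade == "A,C"], 58)
  expect_false("A,D" %in% js$clade)  # clade in none is absent (JS 0)
  all_t1 <- jackknife_support(replicate(10, t1, simplify = FALSE))
  expect_equal(all_t1$js[all_t1$clade == "A,B"], 100)
})

test_that("pairwise identity masks gaps and unknowns", {
  m <- rbind(a = c("A", "C", "-", "D"),
             b = c("A", "C", "X", "D"),
             c = c("A", "C", "X", "D"))
  m[m == "X"] <- "?"
  expect_equal(pairwise_identity(m, "a", "b"), 100)
  expect_equal(pairwise_identity(m, "b", "c"), 100)
  m2 <- rbind(a = c("A", "C", "G", "D"), b = c("A", "C", "G", "E"))
  expect_equal(pairwise_identity(m2, "a", "b"), 75)
  expect_equal(pairwise_identity(m2, "b", "a"), 75)
  m3 <- rbind(a = c("-", "?"), b = c("A", "A"))
  expect_error(pairwise_identity(m3, "a", "b"), "comparable")
})
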