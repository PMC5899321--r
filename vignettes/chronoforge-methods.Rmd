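---
title: "Models and methods in chronoforge"
author: "chronoforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in chronoforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chronoforge implements the full chain of methods behind a Bayesian
phylogenomic timescale: supermatrix assembly from per-gene amino-acid
alignments, site-heterogeneous substitution models, MCMC over topologies
and over divergence times, cross-validation model comparison, and the
downstream rate analyses. This vignette records the models, the
parameters that matter, and the design decisions taken where the
methodology leaves genuine freedom.

## Supermatrix assembly

Per-gene alignments (FASTA or relaxed sequential PHYLIP) are merged into
one OTU × site character matrix. An OTU may be a *chimera*: its row is
filled gene-by-gene from an ordered list of source species. When several
sources carry a gene, the default rule keeps the *slowest-evolving*
sequence — the candidate with the smallest mean pairwise
maximum-likelihood distance to the background taxa of that gene, the
distance being the maximizer of the two-sequence likelihood under WAG
with frequencies estimated from the pair ("+F"). The aggregation over
background taxa (mean, with max as an option) is our choice; the
selection criterion itself is standard. Genes absent from more than
`max_missing = 15` OTUs are dropped (inclusive boundary: exactly 15
missing is kept). Missing-data percentages count both gaps (`-`) and
unknowns (`?`, plus normalized B/Z/J/U/O) as missing; a flag restricts
the count to unknowns only, since the cell classes are not universally
defined. Partitions are half-open 0-based internally and 1-based
inclusive in reports.

The gene jackknife draws, per replicate, `k = 130` of the genes without
replacement (independent across replicates, reproducible by seed);
jackknife support (JS) is the percentage of replicate consensus trees
containing a clade.

## Substitution models and likelihood

All models share the reversible generator `Q[i,j] = rho[i,j] * pi[j]`
scaled to one expected substitution per unit branch length. Site-rate
heterogeneity is the equal-weight discrete gamma with `K = 4` categories;
category rates are conditional bin means (bin medians behind a flag),
renormalized to mean exactly one. The gamma shape `alpha` is estimated by
default under a log-uniform prior on `[0.01, 100]`.

- Poisson/F81: uniform exchangeabilities and frequencies.
- LG, WAG: the published empirical matrices, shipped as plain-text
  PAML-format tables under `inst/extdata/` so the package never needs
  network access.
- GTR: free symmetric exchangeabilities (flat Dirichlet prior over the
  normalized lower triangle) and free frequencies.
- CAT-F81 / CAT-GTR: a Dirichlet-process mixture over equilibrium
  profiles. Each site holds an allocation to one profile; allocations are
  resampled by Gibbs with `m = 3` auxiliary components standing in for
  the prior predictive (the auxiliary draws are refreshed per sweep, a
  standard practical variant). The base measure is symmetric
  Dirichlet(1); the concentration gets an exponential hyperprior with
  mean 10. Component profiles are updated by Metropolis-Hastings,
  alternating a local Dirichlet random walk with an empirical
  independence proposal centred on the component's per-site residue
  counts (each site contributing total weight one); both proposals carry
  exact Hastings corrections.

The likelihood is Felsenstein pruning with per-node rescaling against
underflow; gap/unknown cells contribute all-ones partial vectors, and a
zero-length branch uses an exact identity transition matrix. Identical
site patterns are collapsed and weighted for site-homogeneous models
(CAT keeps per-site columns because allocations differ and move). The
kernel is compiled (Rcpp) with the single-component propagation routed
through BLAS `dgemm`, and maintains an undo log so Metropolis rejections
restore cached partials instead of recomputing. The pruning result is
checked against exhaustive enumeration over all internal-state
combinations on 4–5-taxon cases to 1e-10 in the test suite.

## Clock models and priors for dating

Time runs in Mya before present; tips sit at age 0; there is no tip
dating. The three clock models:

- CL: one global rate `mu_r` (substitutions/site/Mya), log-uniform prior.
- LN (autocorrelated log-normal): child log-rates are normal around the
  parent with variance `sigma2 * dt` and mean shifted by
  `-sigma2 * dt / 2`, so `E[r_child | r_parent] = r_parent`; the root
  rate is log-normal around `mu_r`. The effective rate of a branch is
  the arithmetic mean of its endpoint rates (geometric mean behind a
  flag); branch substitution length is duration times that rate
  (trapezoidal integration).
- UGAM: i.i.d. branch rates, Gamma with mean `mu_r` and variance
  `nu * mu_r^2`; `nu = 0` collapses to CL.

`sigma2` and `nu` carry exponential(mean 1) hyperpriors — weakly
informative on the scale where realistic per-branch log-rate standard
deviations over tens of Mya are fractions of a unit.

Node ages are conditioned birth-death: given the root age `T` and the
taxon count, non-root internal ages are i.i.d. with density
`q'(t)/q(T)`, `q(t) = (1 - e^{-rt}) / (lambda - mu e^{-rt})`,
`r = lambda - mu`, multiplied by the parent-older-than-child indicator.
`lambda` and `mu` have exponential hyperpriors with means 0.1 and 0.05
per lineage per Mya (weakly informative at the ~540-Mya scale), with
`lambda > mu` enforced. The root age prior is exponential with mean
540 Mya.

Soft calibrations are flat on `[min, max]` with exponential tails. Read
as a density, a two-sided bound places mass `1 - 2*eps` on the plateau
(`eps = 0.025` per side by default); the tail scale follows from the
plateau width. A minimum-only bound has no natural width, so its tail
scale uses the bound's own age as the reference width — an explicit
package convention, isolated behind the `calibration()` constructor. The
packaged `calibrations_deutero13.tsv` transcribes thirteen
vertebrate-plus-echinoderm style constraints (e.g. a 519–581 Mya chordate
interval, a 255 Mya echinoid minimum), anchored by pairs of genus names.

## The samplers

One cycle of the phylogram sampler sweeps every branch with a
multiplicative proposal, then applies the scheduled topology moves (two
per cycle by default: rooted NNI, including swaps across a two-child
root, and SPR with uniform insertion and the corresponding Hastings
ratio), one CAT sweep where applicable, and the hyperparameter block.
Branch lengths carry an exponential(rate 10) prior.

The dating sampler holds the topology fixed and updates: each internal
node age (alternating a uniform-window slide with a gap multiplier — the
multiplier mixes well when the conditional concentrates near one end of
the window), the root-gap, a whole-tree age scaling, each lineage rate,
a global rate scaling, the clock variance, and the diversification
rates. A *joint time-rate rescaling* (ages × m, rates × 1/m) leaves every
branch substitution length — hence the likelihood — unchanged and walks
the chain along the rate–time ridge; without it, chains on
rate-confounded posteriors anchor near their initialization and
credibility intervals undercover. It costs no likelihood evaluation and
is repeated five times per cycle.

Every chain is reproducible from its seed (chain id offsets the seed).
An incremental-computation guard recomputes the log-likelihood from a
fresh engine every 1000 cycles and warns if the incrementally maintained
value drifted beyond 1e-6 relative. Two-chain convergence is summarized
bpcomp-style: the maximum clade-frequency difference (pass below 0.3) and
relative differences of scalar means.

## Cross-validation

Splits are uniform without replacement, either fixed counts (e.g.
10,000 training / 2,000 test sites) or fractions (0.9/0.1, where 90% of
66,593 sites gives the familiar 59,934/6,659). The predictive score is
the log of the posterior-sample average of the test-set likelihood,
computed with a running log-sum-exp — not the average of
log-likelihoods; the alternative is available behind a flag. Scores are
compared pairwise per split; we report the mean and *sample SD* of the
per-replicate differences (labelled as such, since an SD and an SE read
very differently at n = 10).

Two design points matter when the strict clock enters a comparison.
First, on saturated data (branch lengths of several substitutions per
site) all clock models fit equally — the likelihood surface is flat — so
meaningful comparisons need realistic branch lengths (of order one
substitution per site at the deepest paths). Second, with only a root
calibration a strict clock can absorb lineage rate variation by
deforming free node ages; densely calibrated nodes (as in a
well-calibrated vertebrate tree) are what force the misfit to show. The
clock cross-validation benchmark therefore calibrates every internal
node at ±10% of its true age.

## Synthetic benchmarks

`simulate_chronogram()` draws the non-root ages i.i.d. from the
conditioned birth-death distribution (inverse CDF) and builds the ranked
topology by uniform lineage splitting — verified against
forward-simulated conditioned Yule trees. `simulate_rates()` implements
the three clocks plus a lineage-specific elevation preset that
multiplies the expected rate inside a designated subtree (the emulated
effect size is 6.25-fold, tunicate-like). `simulate_alignment()` evolves
sites root-to-tips with Γ₄ site rates and per-site profiles, then
applies missingness as whole taxon-by-gene blocks (transcriptome
incompleteness is block-structured, not i.i.d. per cell) until the
global target (default 20%) is met, never blanking a taxon entirely.

Presets: `tiny` is 8 taxa × 5 genes × 200 sites under Poisson+Γ₄
(`alpha = 0.8`), an LN clock (`mu_r = 2e-3` substitutions/site/Mya,
`sigma2 = 1e-3` — root-to-tip paths of order one substitution per site
at a ~500-Mya root), 20% block missingness, and two calibrations derived
from the true ages at ±10%. `deutero63` is a 63-taxon scaffold whose
tips carry the genus names the calibration fixture anchors to — a
synthetic stand-in topology built in code, with the calibration-relevant
nodes pinned at reference ages compatible with the packaged constraints
and remaining ages interpolated with seeded jitter — over 20 genes × 100
sites, a 4-profile CAT-F81 generator, and the 6.25-fold elevation of the
tunicate-named subtree. Benchmarks regenerate bit-identically from
`(preset, seed)`.

What the benchmarks do *not* emulate: alignment error, orthology
mistakes, compositional drift across lineages, indels, and model
misspecification beyond what the generating model itself encodes. A
passing recovery test therefore validates the inference machinery, not
the biological adequacy of any model for real data.

## Validation scales and numerical choices

The shipped validation (test suite and `scripts/acceptance.R`) uses
problem sizes chosen to exercise every code path at desk scale: 4–5-taxon
exhaustive likelihood checks; 10,000 prior-only samples for the
Kolmogorov–Smirnov sampler checks (balanced 4-tip topology, where the
root marginal is exactly the exponential prior and, with the root fixed,
internal ages are exactly i.i.d. conditioned birth-death); 20 recovery
replicates of the tiny preset with ~1,000-cycle chains; substitution-model
cross-validation at 2,000/500 sites × 10 replicates on 6 taxa; clock
cross-validation at 900/100 sites × 5 replicates on 8 taxa. Empirical
quantiles are linear-interpolation (R type 7) — note that interpolated
quantiles are only approximately invariant under sample duplication, and
that the equal-probability gamma bin means sit at about ±1.27 standard
deviations for four categories, so they approach 1 at rate `1/sqrt(alpha)`.
Ties at exactly the consensus threshold are excluded (strict majority),
and branch-length statistics from an ancestral node are path lengths from
the MRCA to each requested tip, excluding the stem branch above the MRCA
(a flag switches to per-branch statistics).

## Known limitations

- The CAT sampler refreshes auxiliary components per sweep rather than
  per site; with very small site counts and weak data this slightly
  favours the current partition.
- The dating sampler assumes a rooted, binary-or-polytomous fixed
  topology; it does not co-estimate topology and dates.
- One-sided calibrations depend on the reference-width convention
  described above; alternative tail shapes (e.g. Cauchy) are not
  implemented.
- Cross-validation reuses the learning-set chains at reduced lengths;
  very short chains can understate the advantage of the richer model.
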