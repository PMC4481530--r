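---
title: "Community phylogenetics and the input-tree problem: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community phylogenetics and the input-tree problem: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commphylo)
```

## The scientific problem

Community phylogenetics asks whether the species that co-occur at a site are
more closely related than chance would predict (phylogenetic clustering,
conventionally read as environmental filtering acting on conserved niches) or
less closely related (overdispersion, conventionally read as competitive
exclusion among similar relatives). Every statistic in this literature is
computed from a phylogeny of the regional species pool, so the answers
inherit whatever error the tree carries — in branch lengths, in topology, in
the amount of sequence behind it. `commphylo` implements the complete
analysis chain for presence/absence community data, together with tools to
perturb trees in controlled ways and to quantify how much the downstream
metrics move: a workflow shaped by studies of DNA-barcode-based phylogenies
for freshwater insect communities, where a single fast mitochondrial marker
must stand in for a multi-gene phylogeny.

## Community structure: MPD, MNTD, NRI, NTI

For a community of $k \ge 2$ species with patristic distance matrix $d$:

* $\mathrm{MPD} = \binom{k}{2}^{-1} \sum_{i<j} d_{ij}$, the mean pairwise
  distance, sensitive to tree-wide structure;
* $\mathrm{MNTD} = k^{-1} \sum_i \min_{j \ne i} d_{ij}$, the mean nearest
  taxon distance, sensitive to structure near the tips.

Each observed value is standardized against a null distribution obtained by
randomizing the community matrix while holding every site's richness (row
sums) and every species' frequency (column sums) fixed — the *independent
swap* algorithm, which repeatedly exchanges $2\times2$ checkerboard
submatrices. The standardized effect sizes are negated so that positive
values mean clustering:

$$\mathrm{NRI} = -\frac{\mathrm{MPD}_{obs} -
\overline{\mathrm{MPD}}_{null}}{\mathrm{sd}(\mathrm{MPD}_{null})},
\qquad
\mathrm{NTI} = -\frac{\mathrm{MNTD}_{obs} -
\overline{\mathrm{MNTD}}_{null}}{\mathrm{sd}(\mathrm{MNTD}_{null})}.$$

Defaults are 1000 randomizations with 1000 successful swaps between
consecutive null matrices, the effort level standard in field studies of
this kind. Two published conventions exist for producing the 1000 null
matrices; `ses_structure()` chains them as a Markov chain by default
(`chained = FALSE` restarts each randomization from the observed matrix).
Swap attempts are capped at 100 per requested swap so degenerate matrices
(no checkerboard anywhere, e.g. perfectly nested ones) terminate with a
warning rather than hang. Rank p-values use the $(k+1)/(n+1)$ estimator,
which cannot return 0. When a null standard deviation is exactly zero —
a community holding every species of a one-site matrix, for instance — the
index is reported as `NA` with reason code `"null_sd_zero"` rather than
as an infinity.

Sites with fewer than two species carry no co-occurrence information and
are removed by `filter_communities()` before analysis, never imputed.
Species present in the community matrix but missing from the distance
matrix abort with a reconciliation message by default; silent pruning must
be requested explicitly (`prune_missing = TRUE`), because a name mismatch
is more often a data error than a modelling decision.

## Phylogenetic signal: Blomberg's K and Pagel's λ

Both statistics model a continuous trait $y$ (here, body-size measures in
mm) on a tree through the Brownian covariance $V$, whose entries are shared
root-to-ancestor path lengths.

**Pagel's λ** rescales the off-diagonal of $V$: $V_\lambda = \lambda V$ off
the diagonal, diagonal unchanged. $\lambda = 0$ is a star phylogeny (no
signal); $\lambda = 1$ is pure Brownian motion. `bm_loglik()` profiles the
root state out as the GLS mean and $\sigma^2$ by maximum likelihood
(divide by $n$, not REML — the likelihood-ratio test needs comparable ML
likelihoods). `fit_lambda()` maximizes over $[0, \lambda_{max}]$ where
$\lambda_{max}$ is the largest value keeping $V_\lambda$ positive definite,
found numerically; for ultrametric trees it exceeds 1, accommodating
fitted values slightly above 1. The interval endpoints are evaluated
explicitly since boundary optima are common. The no-signal test refers
$2(\ell(\hat\lambda) - \ell(0))$ to $\chi^2_1$; because $\lambda = 0$ is a
boundary point this is conservative, which our simulations confirm
(type-I error well under the nominal 5%); the 50:50 mixture correction is
available via `boundary_mix = TRUE` for users who want exact size.

**Blomberg's K** is the observed ratio of the ordinary mean squared error
around the phylogenetically corrected mean to the $V$-weighted one,
divided by its Brownian expectation
$[\mathrm{tr}(V) - n/(\mathbf{1}^\top V^{-1}\mathbf{1})]/(n-1)$; K is 1
under Brownian motion (exactly 1 on a star tree, for any data), below 1
for weaker signal. Significance comes from permuting trait values across
tips; the test statistic is the $V$-weighted MSE (smaller = more signal).
The classic alternative — the variance of phylogenetically independent
contrasts — is available as `statistic = "pic"`; the two agree closely on
the K value (which does not depend on the statistic choice) and typically
on the p-value.

Species on the tree with no trait value (e.g. caseless caddisflies in a
case-length analysis) are pruned from a copy of the tree with a logged
list (`prune_to_traits()`), keeping the trait analysis honest about its
species set.

## Congruence of distance matrices

Because every downstream metric consumes a patristic distance matrix, the
natural question "how different are these candidate trees?" reduces to
"how concordantly do their matrices rank the species pairs?".
`cadm_global()` unfolds each matrix's upper triangle, rank-transforms it
(average ranks for ties), and computes Kendall's W with tie correction,
plus the Friedman-type statistic $\chi^2 = m(p-1)W$. The permutation test
holds the first matrix fixed — the natural design when one tree (a
multi-gene phylogeny, say) is the anchor of comparison — and relabels the
taxa of the others independently, testing the null hypothesis of
incongruence. A-posteriori `mantel_rank()` correlations (Pearson on the
rank-transformed unfolded distances, one-tailed for positive association)
identify which matrices agree; for two matrices $W = (r+1)/2$ exactly on
tie-free data, which the tests exploit as an identity check. The default
999 permutations gives a p-value floor of 0.001.

## Tree perturbations and the cross-tree comparison

Two controlled perturbations probe metric robustness:

* `stretch_deep_branches()` multiplies the deep, between-family part of
  the tree by a factor (2x, 5x, ...), emulating a simplistic correction for
  underestimated deep divergences (e.g. saturation in a mitochondrial
  marker). "Deep" means every branch outside the family crown clades —
  the spanning system connecting family MRCAs to the root, including each
  family stem. The source being emulated does not pin down whether stems
  belong to the stretched set, so `which = "stems"` offers the
  alternative reading; the default is the full deep set because that is
  the branch system whose lengths single-marker trees underestimate.
  Families must be monophyletic (checked, with offending tips listed).
  Within-family patristic distances are provably invariant and
  between-family distances decompose as (within part) + factor x (deep
  part), which the property tests verify explicitly.
* `shuffle_tips()` permutes taxon labels uniformly, a negative control
  that preserves the tree shape and distance multiset while destroying
  all real signal.

To compare metrics across trees, `origin_regression()` regresses a
candidate tree's NRI (or NTI) values on the baseline tree's with the
intercept forced through zero: slope $\sum xy / \sum x^2$ and uncentered
$r^2 = (\sum xy)^2/(\sum x^2 \sum y^2)$. A slope near 1 means the
candidate recovers the scale of the baseline values; high $r^2$ means
little scatter around that proportionality. Communities where either tree
leaves the metric undefined are dropped listwise and counted — the only
handling that keeps both regressions on a common support. The regression
is defined from 2 points up ($\sum x^2 > 0$ required), though meaningful
use starts at far larger community sets.

## The synthetic-data generator

Every stage is testable without any sequence download because the package
generates data with known structure:

* `simulate_yule(n, b, seed)` grows a pure-birth tree to exactly `n` tips,
  extending all branches through the final waiting interval, so trees are
  ultrametric and mean root-to-tip depth has the closed form
  $\sum_{k=2}^{n} 1/(kb)$ — verified by Monte Carlo in the tests.
* `simulate_bm_traits()` draws one multivariate-normal trait vector with
  covariance $\sigma^2 V_\lambda$ via a Cholesky factor.
* `simulate_communities()` assembles sites under three regimes: uniform
  (`random`), distance-decay from a random seed species
  (`clustered`, weights $\propto e^{-s\,d(i,\mathrm{seed})}$), or
  sequential repulsion (`overdispersed`, weights
  $\propto e^{+s\,\min_j d(i,j)}$ over already-selected members $j$).
  Strength 0 collapses all modes to `random`; detection power rises
  with strength, which the tests check as an ordering.

`synthetic_churchill()` assembles a full demonstration survey shaped like
a subarctic freshwater insect study: a 46-species ultrametric tree cut
into 12 family-like clades, 75 sites x 3 monthly visits (225 site-month
records) of which 101 hold two or more species and survive the filter,
and two body-size traits (body length: all 46 species, $\sigma^2 = 8$
mm²/unit depth, root 15 mm, $\lambda = 0.45$; case length: 42 species
after excluding four "caseless" taxa, $\sigma^2 = 12$, root 20 mm,
$\lambda = 0.5$). Assembly is clustered at strength 2 — the moderate
filtering regime such surveys typically report — and richness is uniform
on 2–16. These choices emulate the *design* of a real survey (sample
sizes, trait scales in millimetres, missing-trait species, sparse
site-months for the filter to remove); all values are simulated and no
real observation is reproduced. What passing tests on these data show is
that the estimators are correct and calibrated under the generating
model; they cannot show that any particular field system satisfies that
model — real occurrence data bring detection error, abundance structure
and spatial autocorrelation that the generator deliberately omits.

## Numerical and design choices

* **Distances**: trees are `ape` `"phylo"` objects; patristic matrices
  come from `ape::cophenetic.phylo` and are validated for symmetry
  (1e-12 relative), zero diagonal and unique labels. TN93 distances use
  `ape::dist.dna` with pairwise deletion (the common choice for ragged
  barcode alignments); saturated pairs (non-positive logarithm argument)
  come back `NA`, are listed in an attribute, and block neighbour joining
  until resolved. Gamma rate correction is applied when a shape is given;
  very large shapes converge to the uncorrected distance.
* **Neighbour joining** (`ape::nj`) can produce negative branch length
  estimates on non-additive input; they are clamped to zero with a
  warning because all downstream metrics require non-negative distances.
  The returned tree keeps NJ's arbitrary root but is flagged unrooted.
* **Likelihood**: all Brownian computations go through one Cholesky
  factorization per λ value; the profiled likelihood is exact, not
  iterative, so `optimize()` with tolerance 1e-6 is the only numerical
  search. λ values that break positive definiteness raise an error
  naming the admissible bound.
* **Determinism**: every randomized function takes an explicit `seed`
  and restores the caller's RNG state; there is no silent clock seeding.
  The C++ swap kernel draws from R's own RNG so `set.seed` governs it
  too. Identical seeds give bit-identical results, which the tests
  assert.
* **Performance**: the swap kernel and the per-community MPD/MNTD
  evaluations are small C++ routines (the same division of labour the
  standard null-model packages use), so a full 1000 x 1000 null analysis
  of 500 communities on a 64-tip tree takes seconds. Test and validation
  problem sizes (500 null communities; 100-tip trees with 100–500
  replicates for λ; 200 replicates for K and CADM) were chosen to make
  Monte-Carlo bands tight enough to be meaningful while keeping the whole
  validation suite around two minutes.
* **Interface**: this is a programmatic analysis package in the mold of
  the community-ecology and phylogenetics packages it builds on; the
  exported functions plus `run_pipeline()` (which writes the standard
  congruence / per-tree structure / comparison / signal tables and a
  provenance JSON with seed and config fingerprint) are the interface,
  and `scripts/acceptance.R` shows a complete scripted run.

## Known limitations

* Presence/absence only: no abundance-weighted MPD/MNTD, and only the
  independent-swap null (no frequency-weighted or richness-only nulls).
* λ inference assumes one continuous trait, Gaussian evolution and exact
  tip matching; measurement error is not modelled.
* CADM's permutation scheme fixes the first matrix; results are reported
  relative to that anchor.
* The generator does not simulate sequences, extinction, or abundance;
  tree uncertainty enters only through the explicit perturbations.
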