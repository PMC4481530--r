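# commphylo

Community phylogenetics with an explicit focus on the **input-tree
problem**: how much do the standard metrics of phylogenetic community
structure and trait signal change when the phylogeny behind them changes?

Studies of co-occurrence ask whether the species found together at a site
are more closely related than chance (phylogenetic clustering) or less
(overdispersion). The workhorse statistics — the net relatedness index
(NRI) and nearest taxon index (NTI) — are standardized effect sizes of the
mean pairwise distance (MPD) and mean nearest taxon distance (MNTD) of each
community against an independent-swap null model that preserves site
richness and species frequency:

    NRI = -(MPD_obs  - mean(MPD_null))  / sd(MPD_null)
    NTI = -(MNTD_obs - mean(MNTD_null)) / sd(MNTD_null)

(positive = clustering). All of these are computed from a patristic
distance matrix, so they inherit the error of the tree that produced it.
`commphylo` implements the complete chain needed to study that inheritance:

* **phylogeny handling** — validated Newick I/O, patristic distances, TN93
  sequence distances (gamma-corrected, pairwise deletion), neighbour
  joining, plus two controlled perturbations: deep-branch stretching
  (multiply all between-family branch lengths by 2x, 5x, ...) and tip
  shuffling (a negative control);
* **community structure** — MPD/MNTD, the independent-swap null
  (checkerboard swaps in C++, seeded and bit-reproducible), NRI/NTI with
  rank p-values;
* **trait signal** — Blomberg's K with a permutation test, and Pagel's λ
  by profiled maximum likelihood with a χ²₁ likelihood-ratio test against
  λ = 0;
* **congruence** — CADM (Kendall's W on rank-transformed distance
  matrices, permutation test against a null of incongruence) with
  a-posteriori Mantel correlations;
* **cross-tree comparison** — origin-forced regression (slope Σxy/Σx²,
  uncentered r²) of each candidate tree's NRI/NTI against a baseline
  tree's;
* **synthetic data** — Yule trees, λ-transformed Brownian traits, and
  clustered / overdispersed / random community assembly, so every stage is
  validated against data with known structure, no downloads required.

## Worked example

`synthetic_churchill()` builds a fully synthetic survey shaped like a
subarctic freshwater insect study: a 46-species tree in 12 family-like
clades, 75 sites visited in three months (101 site-months with ≥ 2
species), and two body-size traits in mm. Compare the baseline tree
against perturbed versions of itself:

```r
library(commphylo)

syn  <- synthetic_churchill()
trees <- list(
  baseline    = syn$tree,
  stretched2x = stretch_deep_branches(syn$tree, syn$families, 2),
  stretched5x = stretch_deep_branches(syn$tree, syn$families, 5),
  shuffled    = shuffle_tips(syn$tree, seed = 1))

res <- run_pipeline(trees, "baseline", syn$communities, syn$traits,
                    n_randomizations = 1000, n_swaps = 1000,
                    n_permutations = 999, seed = 2015)

res$congruence
#>          tree mantel_r     p
#> 1 stretched2x  0.89118 0.001
#> 2 stretched5x  0.84841 0.001
#> 3    shuffled  0.00964 0.297

res$comparison
#>          tree metric   slope     r2   n n_dropped
#> 1 stretched2x    nri  0.8816 0.9963 101         0
#> 2 stretched2x    nti  0.9415 0.9875 101         0
#> 3 stretched5x    nri  0.7777 0.9897 101         0
#> 4 stretched5x    nti  0.8797 0.9603 101         0
#> 5    shuffled    nri -0.0250 0.0835 101         0
#> 6    shuffled    nti  0.0798 0.0208 101         0
```

Reading the output: the stretched trees still rank species pairs almost
like the baseline (Mantel r ≈ 0.85–0.89 on rank-transformed distances, p =
0.001), and their NRI/NTI values sit on a tight line through the origin
with slope slightly below 1 — distorting deep branch lengths rescales the
metrics more than it reorders them. The tip-shuffled control behaves as a
control should: congruence ≈ 0, r² ≈ 0.02–0.08. Per-community results live
in `res$structure$baseline` (`nri`, `nti`, rank p-values); trait-signal
results in `res$signal`, where λ detects the simulated signal (λ̂ ≈ 0.32–
0.45 on the unshuffled trees) and drops to exactly 0 with p = 1 on the
shuffled tree. With `outdir =` the same tables are written as TSV plus a
provenance JSON recording seed, parameters and a config fingerprint.

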