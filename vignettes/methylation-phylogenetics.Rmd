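---
title: "Phylogenetic signal and correlated evolution of global DNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic signal and correlated evolution of global DNA methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomethyl)
```

# The question and the data

Global cytosine methylation (%mC) — the percent of genomic cytosines
that carry a methyl group — is measured per sample by HPLC as
`100 * 5mdC / (5mdC + dC)` from the integrated peak areas of
5-methyl-2′-deoxycytidine and 2′-deoxycytidine. Peak areas are in
arbitrary instrument units; the ratio makes the estimate unit-free, and
`percent_methylation()` enforces that invariance exactly.

Species-level data sets assembled from several laboratories are
heterogeneous: different plant parts differ in methylation, experimental
studies report treated plants alongside controls, and multi-genotype
studies report one value per strain. `aggregate_species_means()`
therefore (1) keeps leaf material only, (2) keeps control (or
unclassified) treatments only, (3) averages within species × source ×
genotype, then (4) combines the per-source means into one species mean.
When a species has both a lab and a literature estimate the default is
an unweighted mean of the two source means rather than a pooled sample
mean: the two sources are methodologically distinct blocks and should
not be weighted by their (arbitrary) replicate counts. The pooled
alternative is available (`source_combine = "pooled"`) because the
choice is genuinely open; with balanced replication the two coincide.

Two caveats are deliberate: rows with an *absent* tissue field are
treated as leaf (most literature compilations omit the field precisely
because leaf is the default material), and missing C-values are never
imputed — downstream analyses use complete cases only.

# Trees and the Brownian covariance

All analyses run on rooted `ape` trees. When divergence times are
unknown, `set_unit_branch_lengths()` sets every branch to 1 so that
topology carries all phylogenetic structure; this is the package-wide
convention and the default in `run_full_analysis()`. Polytomies (common
in supertree-derived phylogenies) are resolved into random bifurcation
sequences by `resolve_polytomies()`, with inserted branches given length
1 rather than 0 — zero-length branches would produce zero expected
variances and undefined contrasts. Because the resolution is a stand-in
for unrecoverable fine-scale phylogenetic knowledge, it is seeded:
rerunning with other seeds shows the sensitivity of results to
resolution order instead of hiding it.

Under Brownian motion (BM) with rate $\sigma^2$, tip values are jointly
Gaussian with covariance $\sigma^2 V$, where $v_{ij}$ is the shared
root-to-MRCA path length (`phylo_covariance()`). Patristic distances
satisfy $d_{ij} = v_{ii} + v_{jj} - 2v_{ij}$, which the test suite
checks on random trees.

# The four signal indices

No single statistic captures "phylogenetic signal" well across tree
shapes and evolutionary scenarios, so four complementary indices are
computed concurrently.

**Moran's I** (`morans_i()`) is model-free autocorrelation. The
proximity weighting is a free choice; the default is inverse patristic
distance with no row normalization, and any proximity matrix can be
passed explicitly (row-normalized weights reproduce `ape::Moran.I`).
Under random tip permutation $E[I] = -1/(n-1)$.

**Abouheif's $C_{mean}$** (`abouheif_cmean()`) is Moran's I under the
Abouheif proximity $a_{ij} = 1/\prod_k DD(k)$ (product over internal
nodes on the i–j path of their numbers of direct descendants),
row-normalized. Several standardizations of this matrix circulate; the
row-normalized raw product-rule matrix is the default here, and the raw
and globally standardized variants are exposed via
`abouheif_proximity(normalize=)` so users can match other software
exactly.

**Blomberg's K** (`blomberg_k()`) compares the observed trait variance
around the GLS phylogenetic mean with its BM expectation; K = 1 under
BM, and exactly 1 on any star tree for any non-constant trait (the test
suite asserts this to machine precision).

**Pagel's λ** (`pagel_lambda()`) multiplies the off-diagonal of $V$ by
λ and maximizes the Gaussian likelihood, profiling the mean and rate
analytically. Implementation: with $D = \mathrm{diag}(V)$ and
$C = D^{-1/2} V D^{-1/2}$, one symmetric eigendecomposition of $C$ makes
each λ evaluation $O(n)$, so the ML estimate is cheap enough to be
re-estimated inside every randomization replicate. The search interval
is $[0, \lambda_{max}]$ with
$\lambda_{max} = \min(\min_{i \ne j} \sqrt{v_{ii}v_{jj}}/v_{ij},\;
\text{PD limit},\; 1.5)$: for non-ultrametric trees (unit branch
lengths give one) the likelihood can legitimately peak slightly above
1, so clamping at 1 would bias the estimator downward. The scalar
optimizer runs at tolerance 1e-8 and both interval endpoints are
checked against the interior optimum.

## Randomization testing

`randomization_test()` permutes trait values across tips and reports the
one-sided $p = (r+1)/(n_{reps}+1)$, never zero, with ties counted
against rejection. Permutations are vectorized in chunks, so $10^5$
replicates of I, $C_{mean}$ or K on ~50 species take on the order of a
second each; for λ the statistic recomputed per replicate is itself an
ML fit, so its default is 999 replicates (`n_reps_lambda`), raisable
when wanted.

# Correlated evolution via independent contrasts

`pic_contrasts()` implements Felsenstein's pruning recursion.
Contrast signs are arbitrary, so a deterministic orientation is needed
for two traits to pair up node by node: the minuend at each node is the
child clade containing the lexicographically smallest tip label. The
linear map from tip values to contrasts $T$ satisfies $TVT' = I$ under
BM — the whitening property the test suite verifies on random trees —
which is also why contrasts are regressed *through the origin*:
reflections of individual contrasts are immaterial, and an intercept
would not be invariant to them.

`origin_regression()` reports the slope, F on $(1, n-1)$ df, uncentered
$R^2 = 1 - SS_{res}/\sum c_y^2$ and the adjusted version
$1 - (1-R^2)\,n/(n-1)$ (total df = n for a no-intercept model); the
identities $F = \frac{R^2}{1-R^2}(n-1)$ and the adjusted-$R^2$ formula
are asserted for every fit. Genome sizes are log10-transformed before
contrasts (`log10_transform()`): C-values span orders of magnitude, and
evolutionary change in genome size is naturally proportional.

`origin_permutation_test()` permutes the response contrasts and, by
default, also flips each one's sign with probability ½. The sign-flips
are included because the null distribution of contrasts is symmetric
about zero (directions are arbitrary), so the reflection group is part
of the exchangeability structure; plain permutation (`sign_flip =
FALSE`) is provided for comparison with procedures that omit it. At
n = 4 the test suite checks the Monte-Carlo p against exhaustive
enumeration of all $4! \cdot 2^4 = 384$ permutation-sign combinations.

Normality of contrasts is the key BM diagnostic and is tested with the
standard Shapiro–Wilk W (`shapiro_wilk()`, delegating to
`stats::shapiro.test`). `regression_diagnostics()` adds residual
normality, a residual-vs-fitted table and a scale-location slope —
descriptive only, since mechanical rejection of BM is not the goal.

# The synthetic-data generator

`make_study_fixture()` produces data with the statistical structure
a real angiosperm methylation study would have, so the entire pipeline
is testable end to end:

- **Tree**: 25 family clades (sizes 8, 6, 5, 4, 4, 3, 3, 2, 2, 2 and 15
  singletons; 54 species) arranged on a Yule backbone with Yule
  subtrees, unit branch lengths — a realistic mix of a few well-sampled
  families plus many singletons.
- **%mC**: true Pagel's λ of 0.88 with total rate $\sigma_{yy} = 10$
  per unit branch, centred at 22.5 and clipped to [5, 40]. The λ < 1
  structure is created by adding independent tip noise of variance
  $(1-\lambda)\sigma_{yy} d_i$ to a BM component of rate
  $\lambda\sigma_{yy}$, which gives exactly the λ-model covariance
  $\sigma_{yy}V(0.88)$.
- **C-value**: log10 C-value evolves as the second component of a
  bivariate BM with $\sigma_{xx} = 0.1$ and cross-rate
  $\sigma_{xy} = 0.9$, so the expected through-origin contrast slope is
  $\sigma_{xy}/\sigma_{xx} = 9$ — tip noise on %mC adds residual
  variance but does not bias the slope. Root log10 C-value is 0.5,
  spanning roughly 2–3 orders of magnitude of genome size across tips.
  12 species have their C-value deleted, leaving 42 complete cases.

Two numerical details are deliberate. First, %mC is *shifted* into
range and clipped, not rescaled to the realized range: a data-dependent
rescaling would change the contrast slope from replicate to replicate
and break the slope-recovery contract. The clipped fraction (typically
2–4%) is recorded in `attr(traits, "clip_fraction")` because heavy
clipping would attenuate both λ and the slope. Second, λ-model
simulation goes through a covariance square root
(Cholesky, spectral in semi-definite edge cases) rather than
branch-length rescaling, because the λ transform is defined on $V$, not
on branch lengths, for non-ultrametric trees.

What the generator does *not* emulate: measurement error structure
between laboratories, non-Gaussian trait evolution (bursts,
directional trends), correlated missingness of C-values (missingness is
uniform at random), or realistic taxon names. Tests passing on this
generator therefore validate the statistical machinery under its own
assumptions; they do not certify conclusions about any real data set.

# Problem sizes and reproducibility

Every stochastic function takes an explicit integer seed and is
bit-reproducible given one (R's default Mersenne-Twister;
`make_study_fixture()` derives its topology, trait and missingness
streams from the master seed by fixed offsets). The validation suite
sizes were chosen to keep the full run in tens of seconds while leaving
the Monte-Carlo bands meaningful: λ recovery uses 100 replicates on
200-tip trees (sampling error of the mean ≈ 0.003–0.006), type-I-error
checks use 500 null data sets at 199 permutations each (±2 binomial SD
≈ ±0.02 around 0.05), and slope recovery uses 200 replicates on 60-tip
trees. Oracle-agreement checks (dense-matrix K and λ likelihoods,
loop-computed Moran's I, `ape::pic`, exhaustive permutation
distributions) run at 1e-9 tolerances on trees of ≤ 10 tips.

# Known limitations

- Moran's I depends on an arbitrary proximity choice; results under
  different weightings are not comparable across studies unless the
  weighting is reported. The package defaults are documented above and
  every alternative is reachable by passing an explicit matrix.
- λ estimation assumes $V(\lambda)$ positive definite; trees with
  duplicate tips or zero-length terminal pairs fail with an
  instructive error rather than a silent fix.
- The permutation schemes treat species as exchangeable under the
  null; strong heteroscedasticity across clades (e.g. much noisier
  literature estimates for some families) violates that and is not
  modelled.
- No PGLS, Ornstein–Uhlenbeck, or multivariate (> 2 traits) machinery:
  the scope is signal detection plus bivariate correlated evolution on
  contrasts.
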