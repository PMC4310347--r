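# phylomethyl

Phylogenetically-informed analysis of global DNA cytosine methylation
(%mC) in plants: does interspecific variation in genome-wide methylation
carry a phylogenetic signal, and is it evolutionarily correlated with
genome size?

The package is aimed at comparative biologists who have (a) a rooted
phylogeny of their species sample and (b) species-level estimates of
global cytosine methylation — typically HPLC measurements, where %mC is
estimated per sample from integrated chromatogram peak areas as

    %mC = 100 * 5mdC / (5mdC + dC)

(5mdC = 5-methyl-2′-deoxycytidine, dC = 2′-deoxycytidine) — plus,
optionally, haploid genome sizes (C-values, pg). Everything runs on
ordinary `ape` `"phylo"` trees and plain data frames.

## What it computes

**Trait curation.** `percent_methylation()` and
`aggregate_species_means()` turn heterogeneous per-sample estimates into
one mean per species: leaf tissue only, control treatments only,
genotype averaging within study, and equal weighting of lab and
literature source means when a species has both.
`variance_partition_anova()` partitions sample variance (e.g. among vs.
within species, or between data sources).

**Phylogenetic signal** — the tendency for related species to resemble
each other — tested with four complementary indices:

- *Moran's I*: autocorrelation with proximity weights `w_ij` (default
  inverse patristic distance);
  `I = (n/S0) * Σ_{i≠j} w_ij z_i z_j / Σ z_i²` for centred trait `z`.
- *Abouheif's C_mean*: Moran's I on the row-normalized Abouheif
  proximity, `a_ij = 1 / Π DD(k)` over internal nodes `k` on the path
  between tips i and j (`DD` = number of direct descendants) — topology
  only.
- *Blomberg's K*: observed-to-Brownian-expected variance ratio,
  `K = (MSE0/MSE) / E[MSE0/MSE]`, with the GLS phylogenetic mean and the
  Brownian covariance `V` (`v_ij` = shared root-to-MRCA path length).
  K = 1 under Brownian motion; K = 1 exactly on a star tree.
- *Pagel's λ*: ML multiplier of the off-diagonal of `V`; λ = 0 means
  phylogenetic independence, λ = 1 Brownian motion.

Significance of each index comes from `randomization_test()`: trait
values are permuted across tips and the one-sided p-value is
`(r + 1)/(n_reps + 1)`.

**Correlated evolution.** `pic_contrasts()` computes Felsenstein's
phylogenetically independent contrasts; `origin_regression()` fits the
regression through the origin of %mC contrasts on log10(C-value)
contrasts (slope `β = Σ c_x c_y / Σ c_x²`, F on (1, n−1) df, uncentered
R²), `origin_permutation_test()` permutes and sign-flips the response
contrasts, and `regression_diagnostics()` plus `shapiro_wilk()` check
the Brownian normality assumptions.

**Simulation.** `simulate_yule_tree()`, `simulate_bm()`,
`simulate_lambda_trait()`, `simulate_correlated_bm()` and
`make_study_fixture()` generate trees and traits with known
parameters, so every stage of the analysis can be validated by parameter
recovery.

## Worked example

A synthetic data set with the structure of a typical angiosperm study
(54 species in 25 families, unit branch lengths, 42 species with
C-values) ships with the package:

```r
library(phylomethyl)
tree   <- parse_newick(file = system.file("extdata", "synthetic_tree.nwk",
                                          package = "phylomethyl"))
traits <- read_species_table(system.file("extdata", "synthetic_species.csv",
                                         package = "phylomethyl"))
report <- run_full_analysis(tree, traits, n_reps = 9999,
                            n_reps_lambda = 999, seed = 42)
print(report)
```

which prints:

```
Phylogenetic analysis of global cytosine methylation
  54 species (42 with C-values); %mC mean 24.0, range 10.9-40.0
Signal, %mC:
  Moran's I = 0.1035, randomization p = 0.0001 (9999 reps, seed 144)
  Abouheif's Cmean = 0.5103, randomization p = 0.0001 (9999 reps, seed 145)
  Blomberg's K = 0.6063, randomization p = 0.0005 (9999 reps, seed 146)
  Pagel's lambda = 0.7690, randomization p = 0.002 (999 reps, seed 147)
Signal, C-value (raw scale):
  Moran's I = 0.0188, randomization p = 0.033 (9999 reps, seed 245)
  Abouheif's Cmean = 0.1568, randomization p = 0.0581 (9999 reps, seed 246)
  Blomberg's K = 0.5402, randomization p = 0.016 (9999 reps, seed 247)
  Pagel's lambda = 0.5471, randomization p = 0.048 (999 reps, seed 248)
Contrast normality: W = 0.934 (%mC), 0.974 (log10 C-value)
Regression through the origin (independent contrasts)
  slope = 9.17 +/- 1.262 (SE), n = 41
  F(1, 40) = 52.79, parametric p = 8.019e-09
  R2 = 0.5689, adjusted R2 = 0.5582
Permutation test (permute + sign-flip): F_obs = 52.79, p = 0.0001 (9999 reps)
Residual normality: W = 0.9533, p = 0.09108; scale-location slope = 0.01094
```

Reading the output: all four indices reject the no-signal null for %mC
— related species have similar methylation levels — and the contrast
regression slope ≈ 9 means a ten-fold increase in genome size is
associated with an increase of about 9 percentage points in %mC on this
synthetic data set (which was generated with a true contrast slope of 9
and λ = 0.88, so the pipeline is recovering the built-in parameters).
`write_report_json(report, "report.json")` serializes everything,
including every seed and replicate count.

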