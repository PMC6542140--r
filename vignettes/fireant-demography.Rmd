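---
title: "Coalescent demographic inference for invasive fire ants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent demographic inference for invasive fire ants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireantdemog)
```

## The scientific problem

Two South American fire ants, *Solenopsis invicta* and *S. richteri*, were
introduced into the southern USA early in the 20th century and have become
textbook invasive species. Three demographic questions about them are
addressed by this package:

1. **Did the two species exchange genes after they split?** Answered by a
   full maximum-likelihood comparison, on three-sequence alignments
   (two ingroup RAD haplotypes plus a *S. fugax* outgroup), of a
   complete-isolation multispecies-coalescent model against an
   isolation-with-migration (IM) model, followed by a likelihood-ratio
   test (LRT).
2. **How severe was the introduction bottleneck?** Answered by rejection
   approximate Bayesian computation (ABC) with local-linear regression
   adjustment under a four-population scenario: a large native source
   cluster, a second native cluster, and the introduced population passing
   through a founder population of size `n_f` for `t_b` generations.
3. **What do the scaled estimates mean in real units?** A conversion layer
   turns coalescent-scale estimates (τ in expected substitutions per site,
   θ = k·μ·Ne) into generations, years, effective sizes, and — for the
   founder — numbers of singly-mated queens.

The package also implements the upstream RAD-seq SNP filters and the
DIYABC-style summary statistics the ABC consumes, plus synthetic-data
generators that emulate the study's data at desk scale, so that every stage
is testable without any sequence download.

## Models and assumptions

### Isolation vs isolation-with-migration on triplets

Each locus is an independent 96-bp three-sequence alignment with a pair
configuration: II (two *invicta*), RR (two *richteri*), or RI (one of
each). The gene tree of a triplet has two node times: `t_inner` (first
coalescence) and `t_outer` (coalescence with the outgroup lineage, only
possible after the root divergence `tau_root`). Under the null model a
same-species pair coalesces before the species divergence `tau_ir` at rate
`2/theta_species`; an RI pair cannot coalesce before `tau_ir`. Under the
IM model the two ingroup lineages additionally migrate on `(0, tau_ir)`:
a lineage in *invicta* jumps to *richteri* at rate `4*mig_ab/theta_inv`
per unit of mutational time (so `mig_ab` is expected migrant individuals
per generation), and symmetrically. The three location configurations
(both-in-A, both-in-B, split) form a continuous-time Markov chain whose
matrix exponential gives the pre-divergence coalescence density; after
`tau_ir` both models are identical (ancestral population `theta_anc`,
then the root population `theta_root` with three equally likely pairings
when all three lineages survive to `tau_root`).

Sequences evolve by JC69; the likelihood of an alignment given a gene tree
depends only on the counts of five site-pattern classes (all equal, a=b,
a=out, b=out, all different), which makes the per-locus integral a small
matrix product. Sites containing `N` are treated as missing and skipped.
Assumptions worth noting: no recombination within a locus, free
recombination between loci, equal base frequencies (JC69), and a single
pooled analysis of the three configuration classes with shared parameters.

**Numerical integration.** The marginal likelihood of a locus integrates
the gene-tree density against the alignment likelihood over `(t_inner,
t_outer)`. Each time dimension is integrated by K-point Gauss–Legendre
(default `quadrature_points = 16`, the setting used for the study's
production runs) applied directly in time over each epoch, with
semi-infinite epochs truncated at 25 mean waiting times (relative
truncation error ~1e-11) and split into two geometric panels (boundary at
6 mean waiting times). The two-panel design matters: the
alignment-likelihood factor decays at a rate set by the site-pattern
counts, which differs locus by locus, so no single exponential change of
variables is uniformly accurate; panels in plain time keep the integrand
entire and the rule converges superexponentially for every locus (the
package's self-convergence check bounds `|lnL(K=16) − lnL(K=32)|` per
locus below 1e-4; in practice it is below 1e-9 at the default parameter
scales).

**Optimization.** Both models are maximized over log-transformed
parameters (`tau_root` is parameterized as `tau_ir + exp(x)` so the order
constraint always holds) with Nelder–Mead from `n_starts` jittered
moment-based starts (JC69-corrected pairwise distances). The IM fit is
conventionally started from the null fit's optimum with a weak-migration
seed, which enforces the nesting `lnL_IM >= lnL_null` in practice; the
LRT uses `2*(lnL_IM − lnL_null)` against a chi-square with 2 degrees of
freedom (two directional rates). Because the rates are constrained to be
non-negative, the chi-square reference is conservative (the boundary
mixture would put probability mass at zero), which the type-I-error test
acknowledges by asserting a rejection rate at most twice the nominal 5%.

### The four-population ABC scenario

Backwards in time: the introduced population (size `n_i`) switches to the
founder size `n_f` at `t_i − t_b` generations, merges into the native
source cluster (size `n_n1`) at the introduction time `t_i`, and the
second native cluster (size `n_n2`) merges into the source at `t_d`.
Sizes are effective diploid-equivalent individuals; haplodiploidy is
handled entirely at interpretation time through θ = 3μNe (a design choice
that keeps the simulator standard and matches how the original analysis
applied the correction).

Each locus carries exactly one biallelic SNP: a single mutation is placed
on the simulated genealogy with probability proportional to branch
length. Because every branch lies below the pooled-sample MRCA, the
pooled sample is always polymorphic — the analog of analyzing a SNP
catalog — while within-population monomorphism still occurs and carries
the bottleneck signal. The simulator is continuous-time (no per-generation
Wright–Fisher discretization) and is compiled (Rcpp), since a reference
table multiplies thousands of trees by tens of thousands of draws.

**Priors** (the study's stated ranges where given): `t_i ~ U(0, 180)`
generations, `n_f ~ U(1, 500)`, `t_b ~ U(0, 40)`; the weakly informed
`n_n1`, `n_n2`, `n_i` are log-uniform on `(1e2, 1e8)` and `t_d`
log-uniform on `(180, 1e6)` — wide supports spanning several orders of
magnitude chosen to bracket the plausible range for these populations
(the published point estimates fall one to two orders of magnitude inside
both ends). Draws violating `t_b <= t_i <= t_d` are rejected and
resampled. Truncated normal priors are available as a configuration
option; the default is uniform because the study specifies hard ranges
but no means or standard deviations.

**Summary statistics** (18, fixed order): for each native cluster the
proportion of monomorphic loci, mean and variance of gene diversity over
polymorphic loci, and mean gene diversity over all loci; for the
introduced cluster only the monomorphic proportion and the overall mean
(a newly founded population is poorly served by the polymorphic-locus
moments); for the two pairs that split directly from each other
(source–native2 and source–introduced) the ratio-of-averages mean
Weir–Cockerham F_ST, the proportion of "null" per-locus estimates
(θ̂ ≤ 0 — the estimator is not clipped at zero), and the mean and
variance of the strictly positive remainder. Gene diversity is Nei's
unbiased form `n/(n−1)·(1 − Σp²)` on gene copies.

**ABC.** Distances are Euclidean on statistics standardized by the
reference table's median absolute deviation (constant columns excluded);
exactly `ceiling(tolerance · n_sims)` rows are retained (1% by default,
the study's setting). Retained particles get the Beaumont local-linear
adjustment: Epanechnikov weights on distance, weighted least squares of
each parameter on the centered statistics, particles shifted to the
prediction at the observation plus residuals. Parameters with log-uniform
priors are adjusted on the log scale (the standard DIYABC practice, which
also prevents negative sizes), and all adjusted values are clamped to the
prior support. Adjustment is skipped with a warning when fewer than
`3·(dim+1)` particles are retained, because a near-saturated regression
collapses the posterior spuriously. The MAP is the mode of a weighted
Gaussian KDE (Silverman `nrd0` bandwidth); intervals are weighted
2.5/97.5% quantiles. Goodness of fit projects a random 10% of the
simulated statistic vectors with the observation onto principal
components and reports the observation's Mahalanobis-distance percentile.

### Conversion layer

`generations = tau / mu` with `mu = 3.4e-9` per site per generation
(95% CI 2.2e-9–4.9e-9, a direct honey-bee estimate, the closest
hymenopteran available); `Ne = theta / (3*mu)` for haplodiploids
(`4*mu` for diploids); `years = generations × 6` (generation time 3–6
years; 6 is the reporting average). Confidence intervals combine the
estimate's CI with the mutation-rate CI by interval arithmetic — the
lower bound of a time is `tau_low / mu_high` and the upper
`tau_high / mu_low` — which is the rule that reproduces the published
interval endpoints exactly before display rounding. Displayed values
default to 2 significant figures.

Queens: with singly-mated haplodiploid queens, `Ne = 1.5 * Nf`, so a
founder effective size maps to `ceiling(ne / 1.5)` founding queens
(ceiling reproduces all three published values: 39→26, 14→10, 139→93,
whereas nearest-integer rounding would give 9 for 14). A note on the
breeder formula: the general haplodiploid effective size implemented here
is the standard Wright/Crozier `Ne = 9·Nf·Nm / (4·Nf + 2·Nm)`, which is
the form that reduces to `1.5·Nf` at `Nm = Nf`; a variant sometimes
(mis)printed as `4·Nf·Nm/(2·Nf+4·Nm)` cannot produce that ratio and is
inconsistent with the queen counts above, so it is not used.

## What the synthetic data emulate — and what they do not

`make_study_like_genotypes()` draws three clusters under a known scenario
(defaults: source 1.2e7, second cluster 2.5e5, founder 39 for 2
generations, introduction 120 generations ago, divergence 8e4) with
negative-binomial read depths around 12x and sample/locus-structured
missingness, at ~40 samples × ~1500 loci at full desk scale.
`make_triplet_fixture()` simulates triplets at the shipped estimates
(τ ≈ 6.5e-4 and 8.4e-3; per-species θ of a few 1e-3), 2000 loci by
default. Fixtures are bit-reproducible from seed + manifest.

They do **not** emulate read-level error, reference-mapping artifacts,
linked selection, allele dropout correlated with divergence, or
ascertainment of the SNP catalog; passing tests demonstrate the
correctness and calibration of the inference machinery under the model,
not robustness to those real-data complications.

## Problem sizes and test design

The package's default problem sizes are desk-scale choices: ABC reference
tables of 20,000 simulations at ~200 loci for calibration experiments
(the production-scale 892,000 × 6389 remains a configuration value, not a
code constant), IM fits on 2,000 triplets, 50-replicate null studies at
200 loci for the size of the LRT, and a coverage study of 30 replicate
truths sharing one reference table (the standard design for ABC
calibration: the pseudo-observed datasets are drawn from the prior, so
nominal coverage is expected if the pipeline is sound). Oracles are
independent routes to the same quantity: pair-enumeration gene diversity,
a hand-transcribed Weir–Cockerham estimator, an independent plain-R
coalescent for the simulator, Monte-Carlo gene-tree integration for the
quadrature likelihood, and brute-force sorts/normal equations for the
ABC internals.

## Degenerate inputs and tie-breaks

Spacing thinning is greedy keep-first within a contig (deterministic; the
requirement is only a minimum distance). Rejection ties are broken by row
index. All-missing loci are excluded from MAF and diversity; populations
with no polymorphic locus report a zero variance with a warning. A locus
monomorphic across both populations of a pair has no defined F_ST and is
excluded from the pair statistics; simulations whose statistic vector
contains any undefined entry are dropped from the reference table with a
warning (a corner of prior space where a population contributes no
variable locus). `N` bases are allowed in triplets and skipped per site.
Migration rates of exactly 0 reduce the IM machinery to the closed-form
null expressions.

## Known limitations

- The IM migration window `(0, tau_ir)` is short for these species, so
  only substantial migrant numbers are detectable at desk-scale locus
  counts; the LRT is conservative near the `M = 0` boundary.
- Regression-adjusted ABC intervals are approximate; with 18 statistics
  and 1% retention the adjustment can mildly undercover for the least
  identifiable parameters (the contemporary introduced size and the two
  times whose posteriors track their priors, as the original analysis
  also observed).
- JC69 is the only substitution model; for loci this short and this
  recently diverged the distance differences against HKY-type models are
  negligible relative to coalescent noise.
- Interval arithmetic propagates the mutation-rate CI as hard bounds, not
  as a distribution; no resampling of μ is attempted.
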