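---
title: "Updating the reference population in genomic selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Updating the reference population in genomic selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genomic selection predicts the breeding value of young, unphenotyped
candidates from marker genotypes, using prediction equations trained on a
*reference population* of individuals with both genotypes and phenotypes.
Because phenotyping is the expensive step, only a limited number of new
individuals can be added to the reference each generation, and the choice of
*which* individuals to add feeds back on the breeding population: it changes
the prediction equations, hence the ranking of candidates, hence the genetic
merit and the genetic diversity of the next generation.

`gsrefresh` implements a closed dairy-cattle-style breeding scheme in which
that choice can be made three ways each generation:

* **random** — draw the update group uniformly from the candidates;
* **truncation** — take the candidates with the highest genomic estimated
  breeding values (GEBVs);
* **oc** — optimal contributions: maximize the group's mean GEBV subject to
  a cap on the expected rate of inbreeding, with a minimum-coancestry
  fallback when the cap is unattainable.

The package simulates the whole loop forward in time and measures, per
generation and replicate: mean true breeding value, observed marker
heterozygosity, pedigree inbreeding, standardized prediction bias, and the
effective population size of the reference.

## Models

### Relationship matrices

Two genomic relationship matrices are built from marker dosages
$x_{ij} \in \{0,1,2\}$ (QTL are never included — relationship and diversity
computations mirror chip-based evaluation):

* VanRaden: $G = ZZ' / 2\sum_i p_i(1-p_i)$ with $Z$ the dosage matrix
  centred at $2p_i$.  Used for GBLUP.
* Allele-sharing similarity: $G_{jk} = \frac{2}{N}\sum_i (x_{ij}-1)(x_{ik}-1)$
  over $N$ markers.  Used for the optimal-contribution step, where it has
  been reported to conserve overall diversity better.  Setting all $p_i$ to
  0.5 in the VanRaden construction reproduces it exactly; that identity is
  property-tested.

Marker quality control (call rate > 90%, Hardy–Weinberg equilibrium
chi-square p ≥ 1e-4 on the three genotype classes, minor allele frequency
> 1%) is available as `qc_filter()` for externally supplied genotypes; the
simulator itself produces complete dosages and only drops markers fixed in
the founders.

### GBLUP with fixed variance components

`fit_gblup()` solves the weighted single-trait mixed-model equations
$(W/\sigma^2_e + G^{-1}/\sigma^2_g)\hat g = W(y-\mu 1)/\sigma^2_e$ with the
variance components fixed (no REML), an overall generalized-least-squares
mean $\mu$, and record weights $w$ that scale the residual variance (the
progeny-record analogue; simulated records default to weight 1).  The
implementation uses the algebraically identical variance form
$\hat g = \sigma^2_g G V^{-1}(y-\mu 1)$, $V = \sigma^2_g G + \sigma^2_e
W^{-1}$, so one Cholesky factorization serves the mean, the reference GEBVs
and candidate prediction.  Candidates are predicted by projection,
$\hat g_c = G_{cross} G_{ref}^{-1}\hat g_{ref}$, which equals including them
as zero-weight records in a joint solve; the equivalence is a test, not an
assumption.

A mean is always fitted even though the phenotypes are treated as
pre-corrected: on synthetic data it converges to approximately zero and it
makes the fit robust to a shifted trait scale.

### Optimal contributions

For candidate GEBVs $\hat g$ and a relationship matrix $G$, the optimizer
maximizes $c'\hat g$ over $c \ge 0$, $\sum c = 1$, subject to
$\Delta F(c) \le \Delta F_{max}$ where

$$\Delta F(c) = \frac{c'Gc/2 - \bar f_t}{1 - \bar f_t}.$$

$c'Gc/2$ is the group coancestry of the selected set — the expected
inbreeding of offspring bred from it — and $\bar f_t$ is the current mean
inbreeding proxy.  **The baseline must be on the same scale as $G$**: with
the similarity matrix, whose entries are nonzero even for unrelated
individuals, the scheme uses the current cohort's own mean coancestry under
uniform contributions, $\bar f_t = \overline{G}/2$, so the 1% cap (the FAO
recommendation, the package default) constrains the *increase* over the
current generation.  This mapping of the rate-of-inbreeding constraint onto a concrete formula
is an explicit, logged package convention; other optimal-contribution
implementations differ in how they anchor the baseline.

The solver follows the classical Lagrangian scheme: on the current active
set, $c = G^{-1}(\hat g - \lambda_0 1)/\lambda$ with $\lambda, \lambda_0$
determined in closed form by the two equality constraints; negative
contributions are zeroed iteratively (cap: 10 × candidate count).  Because
elimination alone can terminate at a non-optimal vertex, a
Karush–Kuhn–Tucker check reintroduces any zeroed candidate whose multiplier
is violated.  Three regimes are distinguished explicitly: if the top-GEBV
vertex satisfies the cap, it is the optimum; if the minimum-coancestry
solution exceeds the cap, the instance is infeasible and that solution is
returned with `feasible = FALSE` (merit is effectively not considered);
otherwise the cap binds and the closed form applies.  On 3–4 candidate
instances the solution is verified against an exhaustive simplex-grid
search.

Continuous contributions must be turned into a fixed-size update group:
`select_update_group()` takes the largest contributions, breaking ties by
GEBV then id, and admits zero-contribution candidates (again by GEBV) only
when fewer than requested are positive.  With a 1% cap the optimum is
typically supported on a few dozen candidates, so a 150-individual group is
part OC-support, part GEBV ranking — a direct consequence of the
design choice of fixed-size updates, and the main reason the oc and truncation
strategies behave similarly at this scale.

### Evaluation metrics

* Observed heterozygosity: fraction of dosage-1 markers per individual.
* Pedigree inbreeding: Wright's F via two independent algorithms (recursive
  tabular relationship matrix; Meuwissen–Luo style path tracing) that must
  agree to 1e-10.
* Prediction bias: $|GEBV_k - BV_k| / \sigma_G$, with $\sigma_G$ the
  true-breeding-value standard deviation of the evaluated group, recomputed
  per group and generation.
* Effective size: $N_e = 1/(2 f_t)$ with $f_t$ the mean inbreeding *level*,
  the classical inbreeding-level form, kept deliberately even though a
  rate-based definition is more conventional; at $f_t = 0$ the quantity is undefined
  and returned as `NA`, never a number.
* Generation equivalents: $\sum_g n_{known}(g)/2^g$ over ancestor depths.

Per-strategy generation trends are estimated as the mean of per-replicate
ordinary-least-squares slopes with replicate-level standard errors and
normal 95% intervals — a deliberate simplification of the original
mixed-model analysis (random replicate effect, type II ANOVA, least-square
means), which is out of scope; per-replicate OLS is an unbiased estimator of
the same slopes under that model.  An arcsine-square-root transform for the
proportion-scale metrics and an Ne/N covariate are optional.

## The simulator

The founder generator is a documented stand-in for an external
historical-population simulator that is not part of this package.
Defaults: 10 chromosomes × 100 cM, 200 markers + 20 QTL per chromosome
(2,000 markers, 200 QTL), founder allele frequencies Uniform(0.05, 0.95),
and 100 burn-in generations of random mating at census size 500 to build
linkage disequilibrium, after which the population is expanded to 1,000
males + 1,000 females with pedigree erased (founders are unrelated by
definition).  Meiosis follows the Haldane model: Poisson crossover counts
with uniform positions in `sample_gamete()`, and — exactly equivalently at
the locus level — a Markov chain over loci with switch probability
$r = (1-e^{-2d})/2$ in the vectorized bulk path.  QTL effects are drawn
standard normal and rescaled once so the founder TBV variance equals
$\sigma^2_g$ exactly; phenotypes add $N(0, \sigma^2_e)$ noise.  The default
trait is milk-yield-like: $\sigma^2_g$ = 423,390, $\sigma^2_e$ = 987,910,
$h^2$ = 0.3.

The breeding loop per generation: GEBVs of the newest cohort are predicted
from the current reference; from generation 2 on, 150 cohort members enter
the reference (and are phenotyped — entering the reference implies
phenotyping) and the model is refitted; breeders are the top 150 cohort
males and 500 dams (all cohort females plus the best previous dams, each dam
serving at most 2 generations); mating is random with each dam used once and
sires at most ⌈500/150⌉ times; each dam leaves one offspring with
Bernoulli(0.5) sex.  Because the sex draw is stochastic, the pool of
reusable dams can occasionally fall short; the scheme then admits the
youngest over-cap dams by GEBV (logged) rather than shrinking the herd.
Ties everywhere break by GEBV descending, then id ascending.  The reference
grows 1000, 1150, …, 2350 over ten generations and nothing is ever removed
from it.

Pedigree inbreeding inside the scheme is tracked incrementally with an
additive-relationship block over the live cohorts (parents of the next
generation), which is exact and avoids re-traversing the full pedigree each
generation; the standalone `pedigree_inbreeding()` is the reference
implementation it is tested against.

What the generator does *not* emulate: real chip ascertainment and LD
structure, mutation, non-additive architecture, sex chromosomes, selective
genotyping, or the historical selection that shaped real founder
populations.  Passing tests therefore demonstrate internal correctness and
qualitative behaviour of the machinery, not quantitative reproduction of any
real population's trends; in particular, absolute per-generation trend
magnitudes depend on the founder-history settings and are not pinned to
any external benchmark.

## Numerical choices

* A diagonal ridge (default 1e-2, configurable and logged in every fit)
  stabilizes relationship-matrix solves; finite marker sets make G
  rank-deficient whenever individuals outnumber effective marker dimensions.
  The OC solver first attempts an unridged factorization and falls back to
  the ridge only on failure, so exact small cases stay exact.
* Constraint evaluation in the optimizer uses the matrix employed in the
  solve; the reported rate is always evaluated on the raw G, which can only
  fall below the ridged value, keeping the cap conservative.
* Missing dosages are mean-imputed to $2p_i$ before G construction.
* VanRaden allele frequencies inside the scheme are fixed at the founder
  frequencies (the base-population convention), which also permits
  incremental growth of the reference G; markers fixed in the founders are
  excluded once.
* Degenerate inputs error loudly: zero TBV variance at calibration, all
  markers removed by QC, monomorphic denominators, $f_t \ge 1$ baselines,
  infeasible breeder counts.

## Problem sizes used by the tests

The packaged suite runs everything at sizes a desk machine handles in
minutes, chosen once as the package's own desk-scale defaults: the scenario
comparison runs the full default design (150 sires, 500 dams, 2,000
markers, reference 1000 → 2350, 10 generations) with 10 replicates per
strategy and a 30-generation burn-in; the optimizer compliance sweep uses
100 random candidate sets of 20–200; the pedigree-algorithm cross-check uses
50 random pedigrees up to 2,000 individuals; brute-force optimizer oracles
use 3–4 candidates.  The full-scale study design (50 replicates, 100
burn-in generations) is available by raising `n_replicates` and
`n_burnin_generations` in `scheme_config()`.

## Known limitations

* The three updating strategies differ only subtly in this design — the
  update group is one-tenth of a growing reference — so their long-term
  diversity orderings emerge reliably only with many replicates; at 10
  replicates the heterozygosity contrast between oc and truncation is of the
  same order as replicate noise.
* $N_e$ from the inbreeding level (not rate) inflates early-generation
  values and is undefined while founder cohorts dominate.
* Optimal contributions are solved per update, not jointly over the horizon
  (no dynamic OC, no mate allocation, no sex-constrained contribution
  blocks in the scheme path).
* The real-data path (G-matrix, pedigree, breeding values read from files)
  is supported by the readers but no real data ship with the package.
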