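---
title: "Measuring and predicting local adaptation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and predicting local adaptation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptdiff)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, the tunable parameters and their defaults, the
numerical conventions, what the synthetic-data generator does and does not
emulate, and the known limitations of each estimator.

## The scientific setting

Fragmented plant species persist as archipelagos of remnant populations that
differ in size, environment and connectivity. Whether a given population is
*locally adapted* — resident genotypes outperforming immigrants on home
ground — determines how risky it is to source restoration seed from
elsewhere. The package's pipeline quantifies, for a set of populations:
how much quantitative genetic differentiation exists (Q_ST), how much
neutral differentiation (F_ST), how different the home environments are,
and whether those quantities predict the fitness advantage of local over
foreign genotypes measured in paired transplant experiments.

## Quantitative differentiation: pairwise Q_ST

### Model

For one trait and one pair of populations, the observation model is the
two-level nested random-effects ANOVA

y_ijk = μ + P_i + F_ij + e_ijk,

with population effects P_i ~ (0, V_B), maternal-family effects
F_ij ~ (0, V_fam) and residuals e_ijk ~ (0, V_res). Components are estimated
by Henderson's method of moments: observed mean squares for
population, family-within-population and residual strata are equated to
their expectations under the unbalanced design (the Sokal–Rohlf
coefficients), and the resulting triangular system is solved exactly. The
method was chosen over REML deliberately: it is transparent, closed-form,
and on balanced designs reproduces the textbook expected-mean-square
solution, which makes it independently checkable by a brute-force oracle
(the test suite does exactly that). Negative solutions are truncated to
zero after solving; the untruncated values are retained in the result for
bias diagnostics.

Q_ST for the pair is

Q_ST = V_B / (V_B + 2 V_GW),

where V_GW is the within-population *additive genetic* variance. Two
assemblies of V_GW are offered:

* `heritability_scaled` (default): V_GW = h²·V_W with V_W = V_fam + V_res.
  The heritability is defined against total phenotypic variance within
  populations, so this is the assembly consistent with multiplying by h².
  The sib model does not enter the formula under this variant — it can only
  enter through the variance-component fit itself.
* `literal_4x`: V_GW from the family component alone via the classical sib
  coefficients — half-sib families share one quarter of the additive
  variance (V_A = 4·V_fam), full-sib families half (V_A = 2·V_fam). No h²
  is used. This is the assembly to use when no external heritability
  estimate exists.

Both are exposed because the two conventions circulate in the
common-garden literature and they answer slightly different questions;
neither is asserted to be the only defensible reading. With h² = 1 and
V_W equal to the additive variance the default reduces to the classical
V_B/(V_B + 2·V_A) form.

Per-trait heritabilities are a required user input (`h2`): they come from a
separate heritability experiment in any real application, and no internal
default could be anything but arbitrary.

### Parameters that matter

* `h2` — narrow-sense heritability per trait, in [0, 1]. Directly scales
  the denominator: halving h² roughly doubles small Q_ST values.
* `vw` — `"total"` (V_fam + V_res, default) or `"family"` (V_fam only).
* `model`, `formula_variant` — as above.

### Known limitation: pairwise ratio bias

A pairwise fit has exactly one degree of freedom for the among-population
stratum, so V̂_B is proportional to a χ²₁ draw around its expectation. The
raw components are unbiased (the tests verify this over hundreds of
replicates), but Q_ST is a *ratio*, and after truncation at zero and
clamping to [0, 1] the plug-in estimator is biased: downward at large true
Q_ST (Jensen's inequality on a concave ratio), slightly upward at Q_ST = 0
(truncation makes the estimator nonnegative). At the package's study scale
(15 populations × 25 families × 4 offspring, h² = 0.5) the mean pairwise
estimate at a generating Q_ST of 0.6 sits near 0.41–0.44. Averaging the
*components* over replicates before forming the ratio removes the problem
(the acceptance script reports this consistent variant alongside), but for
a single field data set no such averaging is available: pairwise Q_ST
values at this family size should be read as noisy, conservatively small
estimates, which is exactly how the downstream regressions treat them (as
a relative, not absolute, differentiation scale).

## Neutral differentiation: Weir–Cockerham θ

θ is computed per allele and locus from the 1984 variance components a
(among populations), b (among individuals within populations) and c (within
individuals), using allele frequencies, observed heterozygote carriage and
the sample-size correction n_c. Components are summed over alleles and loci
*before* the ratio is taken (ratio of sums); the test suite pins a fixture
where the mean of per-locus ratios differs, because the two are easy to
confuse and only the ratio-of-sums form is the standard multi-locus
estimator. Missing genotypes are excluded per locus; loci monomorphic
across the pair, or untyped in either population, contribute nothing. The
estimator is allowed to go slightly negative — that is a property, not an
error, and the `dist_matrix` container admits it for `kind = "fst"`.

Diversity statistics follow the conventional definitions: H_O as the
fraction of heterozygous individuals, Nei's unbiased
H_E = (2n/(2n−1))(1−Σp̂²), A_e = 1/Σp̂², and F_IS = 1 − H_O/H_E averaged
over polymorphic loci. The simple F_IS form is used rather than the
Weir–Cockerham f; the two can differ at small n, which is documented here
as a deliberate simplification.

ΔK takes externally produced clustering log-likelihood traces
(K, replicate, lnL) and computes |L(K+1) − 2L(K) + L(K−1)| / sd(L(K)) with
the sample (n−1) standard deviation, defined only at interior K. The
clustering itself (Bayesian admixture MCMC) is out of scope by design: ΔK
is a cheap deterministic post-processing step, the MCMC is not.

## Environmental distance

Variables are filtered by significance of pairwise Pearson correlations
(two-tailed t approximation) at P < 0.001, the conventional threshold for
"highly significant". Because the removal *procedure* is rarely printed in
field studies, the package defines one explicitly and tests its
properties: greedily drop the variable in the largest number of offending
pairs, breaking ties by larger mean |r| with its offending partners, then
alphabetically; constant variables are dropped first with reason
`zero variance`. The filter is idempotent — re-filtering the kept set
removes nothing.

Ordination is PCA on the correlation matrix (variables z-scored).
Components are retained by the Kaiser rule (eigenvalue > 1) by default, or
a fixed count when a study's component counts must be matched. Loadings are
varimax-rotated (Kaiser-normalized, tolerance 1e-8, ≤ 1000 iterations) and
scores recomputed from the rotated axes; with one retained component
rotation is a no-op. Standardization and varimax are conventions, not
facts about any particular study — rotation within the retained subspace
does not change Euclidean score distances at all (a property the tests
assert), so the choice is cosmetic for the distance matrix and matters
only for interpreting loadings. Environmental distance is the pairwise
Euclidean distance between site scores; composite, climate-only and
soil-only matrices are built by variable-set selection from one site table.

Geographic distances are great-circle (haversine) on a sphere of mean
radius 6371.0088 km, in km. Field studies rarely state their distance
computation; straight-line distance is assumed, and no projected coordinate
systems are supported.

## Mantel tests

r is the Pearson correlation of the off-diagonal upper triangles; the null
distribution permutes rows and columns of the second matrix simultaneously
— permuting entries independently would break the distance structure and is
not a valid null. p carries the +1 correction ((extreme + 1)/(n_perm + 1)),
so it is never zero and the test is exact-conservative. Two-tailed is the
default (published Mantel r values are signed but tails are often
unstated); `upper` and `lower` are available. The default 10 000
permutations follow standard practice; every call is seeded, and the test
suite checks the Monte-Carlo p against full 4! enumeration and the
empirical size against the nominal α.

## Transplant analysis

### Differentials

Δ% = 100·(mean_local − mean_foreign)/mean_foreign, positive meaning local
adaptation. Survival uses family-pooled proportions; biomass and
inflorescence counts are averaged over surviving plants. The foreign-mean
denominator is the default and the local-mean alternative is configurable,
because the percentage convention is generally not printed in the field
literature; the algebraic relation between the two is fixed and tested.
A zero denominator falls back to a flagged absolute difference rather than
an infinity.

### Origin × pair tests

The package analyses *family means* with a fixed-effects two-way ANOVA
(origin, pair, origin×pair) instead of a generalized linear mixed model
with random block/row/column/family terms. This is a deliberate design
reduction: family-mean aggregation over a balanced block structure
preserves the origin×pair inference target, is exactly verifiable against
a brute-force sums-of-squares oracle, and requires no iterative fitting.
The cost is that block-level variance is pooled into the residual, so the
tests are mildly conservative when block effects are large. Responses are
transformed per trait before analysis: empirical logit
log((s+0.5)/(n−s+0.5)) of pooled family counts for survival, log(mean+1)
for inflorescence counts, untransformed family means for biomass. Seed
weight can be residualized out first (`seed_weight_covariate`), mirroring
its use as a covariate in maternal-effect-aware designs. Per-pair
local-vs-foreign contrasts use the pooled-error least significant
difference at α = 0.034 — the conventional correlated-test adjustment for
three fitness components (treated as a configuration constant; its
derivation is not re-implemented). Pooled-error LSD was chosen over
per-pair error terms for stability at 15 families per cell.

### Predictor regressions

Forward stepwise selection over {log₁₀ local N, log₁₀ foreign N, log₁₀
distance, environmental distance, Q_ST, F_ST} using
AIC = n·ln(RSS/n) + 2k, at most two terms for twelve data points, final
model by OLS, and the overall F test judged at α = 0.025 (Bonferroni 0.05/2
for designs where two pairs share a home population). Base-10 logarithms
are used for sizes and distances — the base only rescales coefficients.
Numerically collinear candidates (model-matrix condition number > 1e8) are
refused with a warning rather than silently inflating variances. With the
term cap lifted the procedure converges to at most the full OLS fit, and
its selections agree with `stats::step` on the same data (a cross-check in
the tests, not the implementation). AIC-based forward selection overselects
under the null — that is expected behaviour, and the model-level F test at
the corrected α is the intended guard.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the rest of the package is validated under:

* 15 populations, 25 maternal families each (within the realistic 22–30
  band), 4 offspring per family; trait values are grand mean + population
  effect + family effect + residual with configurable (V_B, V_fam, V_res,
  h²). Defaults V_fam = 0.125, V_res = 0.875 put total within-population
  variance at 1 with a half-sib-consistent h² of 0.5 (V_A = 4·V_fam = 0.5).
* 10 multi-allelic loci under the Balding–Nichols model: ancestral
  frequencies Dirichlet(1,…,1), population frequencies
  Dirichlet(p·(1−F)/F), diploid genotypes as two independent draws.
  Balding–Nichols was chosen because it yields a closed-form
  frequency-level differentiation target: the truth record carries the
  large-sample Weir–Cockerham limit computed from the realized
  frequencies, so θ estimates can be scored without re-deriving ground
  truth. Default F = 0.05, a typical outcrossing-herb scale of divergence.
* Two climate zones ~500 km apart (a 2-SD climate shift, matching a
  north–south split), soils drawn iid per site — a mosaic uncorrelated
  with geography, so soil distance shows no isolation by distance (a null
  the tests verify). Optional perfectly collinear variable triplets
  exercise the correlation filter.
* 12 transplant pairs × 15 family pairs × 4 blocks × 2 origins = 1440
  pots. Germination and survival are Bernoulli with logit-scale origin
  effects (baselines 0.85 and 0.95, reflecting benign common-garden
  conditions); biomass is log-normal (σ = 0.3 on the log scale, family
  effects σ = 0.15) with proportional origin effects; inflorescences are
  Poisson with log-scale effects; seed weight is drawn per family at
  ~2.5 mg.

Every generator is a pure function of (config, seed): identical seeds give
bit-identical tables, and the caller's RNG stream is left untouched.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: selfing and self-incompatibility
dynamics, pedigree structure beyond half-sib family effects, null alleles
and scoring error in markers, spatially explicit gene flow (the island
model has no isolation by distance by construction), genotype×environment
interaction in the common garden, and block/row/column micro-environmental
structure (positions are recorded but carry no planted effects).

## Numerical conventions and degenerate inputs

* Distance matrices must be symmetric within 1e-9 (then exactly
  symmetrized), with an exactly zero diagonal and unique labels; geographic
  matrices must be nonnegative, F_ST matrices may be negative.
* Variance components: negative solutions truncated to zero post hoc;
  zero total variance yields all-zero components with a warning;
  populations with a single family are rejected by name, and populations
  with fewer than two families are excluded from pairwise matrices with a
  warning.
* Q_ST is clamped to [0, 1] and defined as 0 when both numerator terms are
  zero. θ is undefined (an error naming the pair) when no co-polymorphic
  locus has data in both populations; F_ST = 1 makes the Rousset transform
  infinite and is rejected with the pair named.
* ΔK requires ≥ 3 consecutive K and ≥ 2 replicates each; zero replicate
  standard deviation at an interior K is an error; an all-zero curvature
  profile is flagged ambiguous rather than silently picking a K.
* The pipeline derives all stage seeds deterministically from one master
  seed, caches matrix stages keyed on input-file hashes, degrades
  gracefully when an input is absent (dependent stages skipped with logged
  warnings), and produces byte-identical reports on rerun.

## Problem sizes used in validation

The test suite validates estimator properties at the full design scale
where the property demands it (Q_ST recovery at 15×25×4 over 200
replicates; θ recovery over 50 seeds per divergence level; Mantel size
over 1000 null datasets) and at reduced scale where only correctness of
arithmetic is at stake (oracle equalities, round trips, hand-computed
fixtures). These sizes are the package's own validation choices and are
stated here so that they can be scaled up by anyone wanting tighter
Monte-Carlo intervals.
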