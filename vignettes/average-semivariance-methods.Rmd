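---
title: "Average-semivariance estimation of marker-associated variance: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average-semivariance estimation of marker-associated variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asvherit)
```

## The models

The package works with two linear mixed models for a population of
`n_G` entries (individuals, families, clones or lines), each phenotyped
`r_G` times for a normally distributed trait. The *entry model*

$$y_{jk} = \mu + G_j + \epsilon_{jk}, \qquad
  G_j \sim N(0, \sigma^2_G),\ \epsilon_{jk} \sim N(0, \sigma^2_\epsilon)$$

estimates the genetic and residual variance. When the entries are
genotyped at a marker locus $M$, the between-entry variation is
partitioned by the *marker model*

$$y_{ijk} = \mu + M_i + G{:}M_{i(j)} + \epsilon_{ijk},$$

with the marker-genotype effect $M_i$ and the entries-nested-in-genotype
effect $G{:}M_{i(j)}$ both random. Multilocus models add one random factor
per locus and per interaction; each interaction is a joint-class
(cell-membership) factor over its observed genotype combinations. With a
single observation per entry the nested term is the residual and
$\sigma^2_G$, $\sigma^2_\epsilon$ and $p$ are no longer separable, but
marker heritability is still estimable against an externally supplied (or
sample) phenotypic variance.

Modelling assumptions: entries are the independent sampling units of a
completely randomized design; genotype classes are opaque categorical
labels (class-mean models, not regression on allele dosage); the residual
covariance is diagonal. Blocking factors, pedigree or genomic
relationships, and multi-trait data are out of scope.

## Why the conventional ratios are biased

On the conventional scale — what ANOVA and REML software returns, called
the average marginal variance (AMV) scale here — the entry-model genetic
variance satisfies an exact identity with the marker-model components:

$$\hat\sigma^2_G = k_M\,\hat\sigma^2_M + \hat\sigma^2_{G:M},$$

where $k_M$ depends only on the design. Sums of squares are additive
across the partition but mean squares are not, and the fraction survives
into the expected values. Any ratio that divides $\hat\sigma^2_M$ by
$\hat\sigma^2_G$ (or by a phenotypic variance containing it) is therefore
inflated by $1/k_M$. The average semivariance (ASV) — half the average
variance of pairwise differences among entries, computed as
$(n_G-1)^{-1}\mathrm{tr}(V D)$ with $D = I - J/n_G$ the mean-centering
projector — assigns each factor the contribution
$\theta_c = k_c\,\hat\sigma^2_c$ with

$$k_c = \frac{\mathrm{tr}(Z_c Z_c^\top D)}{n_G - 1}
      = \frac{n_G - \sum_h n_h^2 / n_G}{n_G - 1}$$

over that factor's observed class counts $n_h$. Entry-level factors
($Z = I$) have $k = 1$; balanced single-locus designs reduce to
$k = df_M\,n_{G:M}/df_G$. Corrected ratios use $\theta$ in the numerator
and are unbiased; on balanced data
$k\,\hat\sigma^2_M + \hat\sigma^2_{G:M}$ reconstitutes $\hat\sigma^2_G$
exactly (a property the test suite asserts at $10^{-10}$).

### Multilocus k

Each factor's k is computed from its own (joint-class) counts via the
trace formula, independently of the other modelled terms. For interaction
factors this is exact. For main effects co-modelled with other loci the
closed-form coefficients contain cross-locus adjustment terms that the
trace formula omits; on real unbalanced data the two can differ in the
second decimal (e.g. a strongly unbalanced three-locus cattle example
where the trace gives 0.343 for a locus reported at 0.35, while the other
two loci agree at 0.41 and 0.54). The trace route was chosen because it
is model-free, exact for single loci and interactions, and extends to any
number of loci; the residual discrepancy is documented rather than
patched.

## Estimators

* `anova_mom()` — closed-form method of moments for balanced data.
  Sums of squares use the classical factorial decomposition; expected
  mean squares are assembled for the all-random model and the components
  solve the triangular EMS system. A single marker factor with unequal
  class counts (but equal replication) is also accepted, using the
  standard unbalanced one-way coefficient
  $(n_G - \sum_h n_h^2/n_G)/df_M$ — the same algebra that produces the
  unbalanced k. Crossed factors with unequal joint counts refuse and
  point to REML. Negative solutions are truncated to zero and flagged
  (`boundary`); the untruncated values are kept in `components_raw`.
* `reml_fit()` — observation-level REML through `lme4::lmer()`, the
  route mainstream software takes; the package's contribution is the
  scale conversion, not the solver. The optimizer is bobyqa with
  `rhoend = 1e-12`: the restricted deviance is flat to machine precision
  within about $10^{-5}$ of the optimum along a 2-df marker direction, so
  the balanced MoM≡REML equivalence is asserted both in parameter space
  (at $10^{-5}$) and in objective space (deviance at the MoM solution
  within $10^{-6}$ of the optimized deviance).
* `fit_entry_model()` — the entry model, closed-form when balanced,
  REML otherwise. Under unequal replication the entry-mean phenotypic
  variance uses the harmonic mean of $r_j$ in the
  $\sigma^2_\epsilon/r_G$ slot (reported with a message); the closed
  form assumes a common $r_G$.

Ratio denominators: when replication permits, $\hat p^*$ and
$\hat H^{2*}_M$ divide by the entry-model $\hat\sigma^2_G$ (the two
candidate denominators $\hat\sigma^2_G$ and
$k\hat\sigma^2_M + \hat\sigma^2_{G:M}$ differ under imbalance, and
published worked examples resolve the choice to the entry model);
otherwise the reconstruction is used. Estimates of $p$ or $H^2_M$ above 1
are reported as-is with a warning, never clipped — an uncorrected value
above 1 is the diagnostic signature of the bias, and clipping a corrected
value would hide a precision problem.

Two-stage versus one-stage: entry means with residual variances
$\hat\sigma^2_\epsilon / r_j$ are exposed (`entry_means()`) as the
semivariance-level summary, but variance components are estimated from
the observation-level models directly. A two-stage generalized
least-squares fit with the first-stage residual covariance held fixed
would need a bespoke REML implementation for no gain at CRD level, where
the two routes coincide for balanced data and differ negligibly
otherwise.

## Uncertainty

`delta_var_ratio()` implements the first-order ratio expansion;
`varcomp_sampling_variances()` feeds it with
$\mathrm{Var}(MS) = 2\,MS^2/df$ mapped through the inverse EMS matrix.
Two different uncertainty targets must not be conflated:

* the **unconditional** variance (across hypothetical populations) is
  what the mean-square chi-square theory measures; with $df_M = 2$ it is
  dominated by the draw of the three class effects, and the tests verify
  it against the empirical variance across independently simulated
  populations;
* the **conditional** variance (given the realized class effects) is what
  `bootstrap_ratio()` measures, because resampling entries with
  replacement — entries being the independent units — holds the class
  structure essentially fixed. It is the right data-driven standard error
  for a single dataset, and it sits well below the unconditional value
  for low-df marker factors.

Because the corrected estimate is exactly $k$ times the uncorrected one,
their variances on shared resamples satisfy the $k^2$ precision ratio
identically; the suite asserts this at $10^{-12}$.

## Fixed-effects comparison

`type1_table()` (all main-effect orders; interactions appended in one
fixed sequence), `type2_table()` and `type3_table()` compute reductions in
error sums of squares from least-squares fits of cell-indicator models,
with partial $R^2 = SS/SS_{\mathrm{total}}$. Type II conditions each term
on every term not containing it (the standard hierarchy rule; a published
table footnote omits one main effect from an interaction's conditioning
set, which is taken as a typo since it contradicts the footnote's own
rule for main effects). Type III uses sum-to-zero contrasts over observed
cells and is flagged when cells are empty, since it is
contrast-dependent there. All three are verified against independent
oracles (`stats::anova`, `car::Anova`) on unbalanced fixtures; every
sequential order telescopes to the same model SS, and the three types
coincide on balanced data.

## The simulation engine

`design_catalog()` encodes 21 study designs: one to three balanced
three-genotype loci at $n_G = 540$, $r_G = 5$ with per-population
heritability drawn uniformly on (0, 1) (designs 1–3); an F2-type 1:2:1
segregation with deterministic expected counts 135:270:135 (design 4);
10% and 33% missing observations (designs 5–6); $n_G = 900$,
$H^2_M = 0.5$ across $r_G \in \{1,2,5,10,20\}$ (7–11); $r_G = 5$,
$H^2_M = 0.5$ across $n_G \in \{450,\dots,7200\}$ (12–16); and
$n_G = 450$, $r_G = 5$ across $H^2_M \in \{0.05,\dots,0.95\}$ (17–21).

Parameterization (the study conditions, fixed once):

* truth lives on the ASV scale: $\theta_M = k_M \sigma^2_M$ and the
  target heritability is $\theta_M / (\theta_M + \sigma^2_{G:M} +
  \sigma^2_\epsilon / r_G)$ — the only convention under which the
  uncorrected estimator's relative bias is $(1-k)/k$ while the corrected
  one is unbiased, since $E[\hat\sigma^2_M] = \sigma^2_M$;
* the entry-mean phenotypic variance is normalized to 1 and the
  non-marker budget is split half/half between $\sigma^2_{G:M}$ and
  $\sigma^2_\epsilon/r_G$ (the relative biases depend only on k and the
  heritability target, not on this split); multilocus targets are split
  equally across marker factors;
* class effects are drawn fresh each population, then centered and scaled
  so the realized between-entry marker variance equals the target
  exactly — each simulated QTL explains exactly its nominal share. With
  unscaled draws a three-class effect vector carries a $\chi^2_2$-shaped
  realized variance, and 1,000-replicate means of $\hat\sigma^2_M$ wander
  by several percent, which is incompatible with reporting a single
  replication-invariant relative bias per design;
* one RNG stream per replicate (`seed + replicate index`), so any
  replicate is reproducible in isolation;
* balanced designs are estimated by method of moments, unbalanced ones by
  REML; the two are required to agree on balanced data.

Relative bias is $(\bar{\hat\theta} - \theta)/\theta$ for fixed-truth
designs. For the varying-heritability designs 1–6 the per-replicate ratio
has no finite mean as the truth approaches zero, so summaries report the
pooled form (mean estimate − mean truth)/mean truth, which equals the
usual RB when truth is fixed.

What the generator emulates: CRD phenotypes with normal entry,
marker-class, and residual effects; deterministic expected genotype
frequencies (balanced, 1:2:1, or post-deletion); missingness completely
at random. What it does not: linkage and recombination, selection or
ascertainment bias, non-normal traits, heteroscedastic residuals,
genotyping error, real LD structure. Passing tests therefore certify the
estimators' algebra and sampling behaviour under the stated models, not
robustness to those violations.

Problem sizes in the checks: the test suite runs the full 21-design
catalog at 100 replicates per design and the headline bias panels at
200 replicates per design, with tolerances of three Monte-Carlo standard
errors computed from the empirical spread; the acceptance script uses
1,000 replicates per design. These sizes put the Monte-Carlo error well
below the effects being measured (the uncorrected inflation is ~0.5; its
standard error at 1,000 replicates is ~0.005).

## Numerical choices and degenerate inputs

* Level ordering is lexicographic everywhere, so indicator matrices and
  fits are bit-reproducible.
* Traces of $Z Z^\top D$ are computed by count arithmetic
  ($n_G - \sum n_h^2/n_G$); dense products appear only in test oracles.
* MoM truncation at zero is flagged, never silent; simulation summaries
  use the reported (truncated) components, matching what constrained REML
  returns in practice.
* A factor with a single observed class is non-estimable and flagged
  ($k = 0$); entries missing a genotype at a modelled locus are excluded
  from that fit only (listwise per model); an all-unreplicated dataset
  routes to the unreplicated pathway instead of the entry model.
* Bootstrap resamples that collapse a modelled factor to one class are
  redrawn and counted.
* Displayed tables round to two decimals; serialized outputs (JSON/TSV)
  keep full precision.

## Limitations

Closed-form multilocus k with cross-locus adjustments is not implemented
(trace formula instead, see above); denominator-df choices for mixed-model
F-tests, genomic-relationship $\sigma^2_G$, selection-bias modelling and
phenotype transformations are out of scope. The delta-method expressions
are the generic first-order ratio expansion with mean-square chi-square
inputs, labelled as such.
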