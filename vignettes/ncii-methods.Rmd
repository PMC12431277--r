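---
title: "Models and methods for North Carolina Design II analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for North Carolina Design II analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nciigen)
```

## The design and the four models

A North Carolina Design II crosses a set of female lines to a set of male
lines; each hybrid carries one female and one male parent, so the genetic
variance among hybrids decomposes into female general combining ability
(GCA), male GCA, and cross-specific specific combining ability (SCA).
`nciigen` analyses trials of such hybrids (plus their selfed parents)
grown in replicates within one or more years, on the motivating scale of
12 females x 14 males with 118 of 168 crosses realised, two years and two
replicates.

All four models have a single fixed intercept; everything else is random
and Gaussian:

* **model 1** (per year, per population): `y = mu + replicate + genotype + e`.
  It provides the genotypic variance and the genotype BLUPs whose adjusted
  means (`mu + BLUP`) feed the heterosis calculations.
* **model 3** (across years, per population): adds year, replicate within
  year and genotype x year, with a separate residual variance per year.
* **model 5** (per year, hybrids): replaces genotype by
  `female GCA + male GCA + SCA`, plus replicate.
* **model 6** (across years, hybrids): model 5 terms plus year, replicate
  within year, and the year interaction of each combining-ability term,
  with per-year residuals.

Treating every term as random (rather than fixed genotype effects) is the
standard choice for incomplete factorials: BLUPs shrink towards zero in
proportion to their information content, which is what makes effects of
parents appearing in few crosses comparable to well-connected ones.

## REML estimation

Variance components are estimated by restricted maximum likelihood on the
P-matrix formulation: with `V = sum_i theta_i Z_i Z_i' + sum_g theta_g D_g`
(the `D_g` being per-year residual indicator blocks),

```
loglik = -1/2 ( log|V| + log|X'V^-1X| + y'Py ),
P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1.
```

The optimiser interleaves two update types:

* **EM steps** `theta <- theta + theta^2/q (y'P Q P y - tr(P Q))`, which
  are monotone in the restricted likelihood and can never leave the
  nonnegative cone — used for the first two iterations and as a fallback;
* **average-information (AI) Newton steps** using
  `AI_ij = 1/2 y'P Q_i P Q_j P y`, which converge quadratically near the
  optimum. A proposed AI step is projected onto the parameter space
  (negative components clamped to zero) and step-halved until the
  likelihood does not decrease; if no acceptable step is found the
  iteration falls back to EM.

Components pressed against the zero boundary with an outward-pointing
gradient are pinned at exactly zero, matching the convention of reporting
boundary estimates as `0.00 +/- 0.00`. Convergence requires a relative
log-likelihood change below `1e-10` *and* a parameter change below `1e-8`
of the phenotypic variance (defaults exposed in `fit_reml()`), within 200
iterations; non-convergence is flagged on the result, not thrown. These
tolerances are deliberately tight so that on balanced designs the
estimates agree with the closed-form ANOVA estimators to at least six
significant digits — the test suite checks this on randomized balanced
layouts and checks unbalanced fits against `lme4` where that engine
applies (single residual). The across-year models assume heterogeneous
per-year residual variances, which is why an in-house engine is needed at
all.

At the optimum, Henderson's mixed-model equations give the intercept, the
BLUP of every random level, and its prediction-error variance (PEV) from
the diagonal of the inverted coefficient matrix. Component standard errors
come from the inverse AI matrix over interior components; boundary
components are reported with SE 0.

BLUP significance uses `t = BLUP/sqrt(PEV)` against the standard normal
reference — residual degrees of freedom in these designs run into the
hundreds, where the normal and t references are indistinguishable; the
reference is a documented choice rather than a parameter. Variance
components are tested by the likelihood-ratio test with the boundary null
mixture `1/2 chi2_0 + 1/2 chi2_1`, the standard distribution for a single
variance component on the boundary of its space.

## Derived statistics

With unrelated inbred parents, Design II theory gives
`sigma2_A = 2 (sigma2_GCA-F + sigma2_GCA-M)` and
`sigma2_D = 4 sigma2_SCA`. Phenotypic variance on an entry-mean basis is
`sigma2_P = sigma2_A + sigma2_D + sigma2_e / r`.

Two genotypic-variance conventions coexist deliberately in
`genetic_summary()`:

* narrow-sense heritability `h2 = sigma2_A / sigma2_P` uses the
  combining-ability decomposition above, as do its parent-specific
  analogues `h2_F = 4 sigma2_GCA-F / sigma2_P` and
  `h2_M = 4 sigma2_GCA-M / sigma2_P`;
* broad-sense heritability and genetic advance use the *genotype-model*
  variance (model 1) with its own residual:
  `H2 = sigma2_G / (sigma2_G + sigma2_e/r)`,
  `GA = i * H2 * sqrt(sigma2_P)`, `GAM = 100 GA / mean`, with `i = 2.06`
  (5% selection intensity). Both paths are exposed explicitly because both
  conventions are in routine use and they answer different questions
  (additive response vs. clonal/hybrid repeatability).

The average degree of dominance is computed as
`D = sqrt(2 sigma2_D / sigma2_A)`; the square root is essential — the
ratio without it is the *squared* degree of dominance and produces values
inconsistent with the dominance-to-additive ratios this statistic is meant
to summarise. `H2` is always propagated unrounded into `GA`; rounding it
to two decimals first changes `GAM` by more than its display precision.

Heterosis uses model-1 adjusted means with parents and hybrids fitted
separately (they are blocked separately in the underlying trials):
`MPH = 100 (F1 - MP)/MP` against the mid-parent mean and
`BPH = 100 (F1 - BP)/BP` against the better parent. "Better" means larger
for all nine minerals — all are scored "more is better"; direction labels
are reported, not imposed, so desirable negative effects (e.g. for sodium)
remain visible. For positive traits `BPH <= MPH` always, strictly when the
parents differ. The pooled heterosis range scans every MPH and BPH entry
across crosses, traits and years.

Association panels use Spearman rank correlation with midranks for ties
and the t-approximation on `n - 2` df for p-values, with no multiplicity
correction across panel cells (raw stars are the convention for these
tables). A series with zero rank variance yields an undefined (NA)
coefficient, never zero. The cross-level sGCA series is the exact sum of
the two parental GCA BLUPs.

## Quality control and descriptives

The outlier screen follows the Holm-adjusted studentized-residual
workflow recommended for plant-breeding trials: per trait, year and
population, a genotype + replicate fixed-effects fit provides externally
studentized residuals, whose two-sided t p-values are Holm-adjusted at
family level 0.05. The screen only flags; removal is the caller's choice
(`run_pipeline()` drops flagged rows by default and records the count in
its manifest). Descriptive statistics (mean, min, max, SE, CV) are
computed on raw observations pooled across years and replicates — for
balanced years the pooled mean then equals the average of per-year means,
a property the tests pin down. The parent-vs-hybrid comparison uses a
Welch t-test when both samples pass Shapiro-Wilk at 0.05 and the Wilcoxon
rank-sum test otherwise.

## The synthetic generator

`simulate_ncii()` draws every random term of model 6 — year, replicate
within year, female GCA, male GCA, SCA, the three year interactions, and
per-year residuals — as independent mean-zero Gaussians with configured
variances and sums them. `study_sim_config(trait)` carries the study
conditions for each of the nine minerals: the across-year hybrid variance
magnitudes, the per-year residual variances, and the population means, on
the published scale (macrominerals g/kg DW, microminerals mg/kg DW).
Replicate-within-year variance is never reported in such tables; the
generator's convention is half the residual variance of the corresponding
year. Selfed parents are emitted as `mu_parent + 2 * (own GCA)` plus
noise — a convention that gives synthetic heterosis a known structure
(the factor 2 is the parental additive value of an inbred line under the
same GCA scale), not a claim about any particular dataset.

What the generator deliberately does **not** emulate: incomplete-block
(alpha-design) structure within replicates, non-Gaussian effects,
epistasis, linkage or marker data, and negative-value truncation is a
simple clamp at zero (relevant only for traits whose mean is within a few
SDs of zero). Passing tests on synthetic data therefore demonstrate
correctness of the estimation machinery under the stated model, not
robustness to field-data pathologies beyond it.

`make_incomplete_factorial()` samples the realised cross subset uniformly
without replacement and redraws until every parent is connected (feasible
whenever the cross count reaches the larger parent-set size) — an
unconnected parent would have no information for its GCA.

## Numerical choices and edge cases

* Constant response: all components are reported as exact zeros with
  `mu = value`; no iteration is attempted.
* Zero-variance terms: BLUPs are exactly 0 with PEV 0 and are excluded
  from the mixed-model equations.
* Estimates are invariant to row permutation and genotype relabelling
  (rows are canonically ordered before design matrices are built).
* `degree_of_dominance()` errors when `sigma2_A = 0` (undefined) and
  `predictability_ratio()` when all three combining-ability components are
  zero, rather than returning 0/0 artifacts.
* Ranks in combining-ability tables break ties by "min"; the ranking is a
  permutation within each parental role.

## Problem sizes used for validation

The packaged validation runs at the study's own scale where that is cheap
(single-year combining-ability fits, 118 crosses x 2 replicates, fit in
well under a second) and at reduced scale where many replicates are
needed: the Monte-Carlo recovery study uses 100 simulated datasets of the
full 12 x 14 / 118 design under the per-year model, and the
property-based checks use 6-8 parents per side. The nine-trait pipeline
check runs per-year analyses for all nine minerals on one simulated
dataset. These sizes are the package's own validation design, chosen to
give stable Monte-Carlo summaries (recovery means settle to within a few
percent) while keeping the full suite fast enough to run on every change.

## Known limitations

* No pedigree or marker relationship matrices; parents are assumed
  unrelated and inbred for the additive/dominance translation.
* No epistatic variance estimation (confounded with dominance in this
  design).
* Standard errors for derived ratios (h2, D, predictability ratio) are
  not produced; they would require a delta method over the full component
  covariance and are rarely decision-relevant for these statistics.
* The across-year broad-sense heritability of hybrids can be computed
  from several inconsistent component sets (combining-ability vs genotype
  decompositions whose estimates need not agree); the package always
  computes it from the genotype-model components it is given.
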