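---
title: "Methods: screening, factor reduction and grey relational ranking of pre-jump height indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, factor reduction and grey relational ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prejump)
```

## The problem

Pre-jump height — the maximal height a trampoline gymnast reaches in the
preparatory vertical bounces before a routine — is shaped by anthropometry,
physical quality, specialized technique, perceptual ability and
psychological state. With cohorts of elite juveniles numbering in the teens,
classical regression on dozens of candidate indicators is hopeless; the
field's approach is (i) to prune the candidate list by expert judgment,
(ii) to collapse each dimension into a few representative indicators by
factor analysis, and (iii) to rank the survivors by how closely their
across-athlete profile tracks the criterion, using grey relational
analysis, a similarity measure designed for exactly this
small-sample, many-indicator regime. `prejump` implements that pipeline
with every threshold explicit and every stage unit-tested.

## Expert screening

Experts score each candidate indicator on a 1–5 importance scale. An item
enters the preliminary set when its rater mean is **strictly** greater than
3.5 points and the panel agrees. "Agreement" is not a standardized
quantity; we operationalize it as an across-rater standard deviation
(divisor $n-1$) of at most 1.0, the common Delphi-style convention, and
expose it as `consensus_rule = "sd_max"` with a configurable cap.
`consensus_rule = "none"` disables it, under which retention is provably
monotone in any single rater's score (a property the test suite exercises).

## Factor reduction of an indicator block

Each primary dimension is reduced separately. The stages, with their gates:

* **KMO sampling adequacy.** With $q_{ij}$ the anti-image (partial)
  correlations obtained from the scaled inverse of the block correlation
  matrix, $KMO = \sum_{i\ne j} r_{ij}^2 / (\sum_{i\ne j} r_{ij}^2 +
  \sum_{i\ne j} q_{ij}^2)$. The block is factored only if $KMO > 0.5$. A
  useful identity: for two variables the partial correlation equals the
  simple correlation, so any 2-indicator block has $KMO = 0.5$ exactly and
  never passes — factors need at least three markers to be adequately
  sampled, which is why the synthetic test blocks use three indicators per
  latent factor.
* **Bartlett's sphericity.** $\chi^2 = -(n-1-(2p+5)/6)\log\det R$ on
  $p(p-1)/2$ degrees of freedom; the gate is $p_{\text{value}} < 0.05$.
  When either diagnostic fails, `reduce_block()` returns a
  diagnostics-failure result carrying the statistics rather than silently
  factoring noise.
* **Extraction.** Principal components of the correlation matrix (no
  iterated communality estimation, matching the SPSS "principal
  components" default). Components with eigenvalue **strictly** greater
  than 1 are retained. Eigenvector signs are fixed by making each column's
  largest-magnitude entry positive; eigenvalue ties keep the
  decomposition's original order.
* **Varimax rotation.** Orthogonal rotation maximizing the variance of
  squared loadings, with Kaiser row normalization on by default (the SPSS
  convention) and convergence tolerance $10^{-9}$. Rotation preserves row
  communalities and the rotation matrix is orthogonal to $10^{-10}$; for
  two components the rotated solution matches a 0.001-radian grid search
  over planar angles, which the suite checks.
* **Representative selection.** Each indicator is assigned to the
  component on which its absolute rotated loading is largest, so every
  indicator lands in exactly one component's list; within a component the
  representative is the assigned indicator with the largest absolute
  loading, required to exceed 0.4. A component whose best loading falls at
  or below 0.4 is flagged as unrepresented rather than given a weak proxy.
  The published block tables do not state how a representative was picked
  when several loadings passed 0.4; max-|loading| is the rule that
  reproduces their "representative / other indicators" structure.

With 16 athletes and a dozen indicators per block the empirical correlation
matrix is near-singular; the module gates on invertibility, and the test
suite runs factor recovery at $n \ge 200$ (five or more athletes per
indicator is a sensible floor for real use).

## Grey relational analysis

Pre-jump height is the standard sequence $x_0$, each indicator an inspected
sequence $x_i$, both over the $k = 1,\dots,n$ athletes. All sequences are
first normalized by dividing by their own mean — which requires strictly
positive means (true of every indicator here; the generator's Gaussian
tails make this a checked precondition rather than an assumption) and makes
grades invariant to each indicator's measurement scale. With
$\Delta_{0i}(k) = |x_0(k) - x_i(k)|$ on normalized data, Deng's coefficient
is

$$\zeta_i(k) = \frac{\Delta_{\min} + p\,\Delta_{\max}}
                    {\Delta_{0i}(k) + p\,\Delta_{\max}},$$

and the grade of indicator $i$ is $\frac1n \sum_k \zeta_i(k)$. Choices that
matter:

* The source formula is printed inline without a fraction bar; the ratio
  above is the standard Deng form and the only reading consistent with
  coefficients lying in $(0, 1]$.
* $\Delta_{\min}$ and $\Delta_{\max}$ are **global** over all indicators
  and athletes. Consequently a grade depends on which other indicators are
  in the table — adding a wildly discrepant indicator inflates
  $\Delta_{\max}$ and compresses everyone else toward 1. This coupling is
  inherent to the method, not a bug.
* The distinguishing coefficient is $p = 0.5$, the conventional value. As
  $p$ grows the $p\Delta_{\max}$ terms dominate and coefficients compress
  toward 1 (monotonically, when $\Delta_{\min} = 0$); the suite asserts
  this.
* If every inspected sequence equals the standard after normalization,
  $\Delta_{\max} = 0$ and all coefficients are defined as 1.
* **No direction alignment.** Negatively oriented indicators (state
  anxiety falls as performance rises) are *not* reflected before analysis:
  the published table pairs a negative Pearson correlation with a high
  grade, which is only possible if no alignment was applied. Mean
  normalization maps both sequences to profiles around 1, and the grade
  measures profile proximity, not signed association — which is also why
  the Pearson column is reported alongside.

Grades above 0.9 are classified strong, below 0.8 weak, and the closed
interval $[0.8, 0.9]$ moderate (both boundaries are moderate). Ranks break
ties by input order.

## The synthetic cohort generator

The study's raw athlete-level table was never deposited; only per-indicator
means and SDs and each indicator's Pearson correlation with pre-jump height
are printed. The generator treats those moments as the study conditions:

* `generate_exact(spec, n, seed)` draws $n \times m$ standard normals,
  centers the columns, whitens against the empirical covariance (giving
  exactly zero mean and identity sample covariance), re-imposes the target
  correlation through its Cholesky factor, and rescales/shifts to the
  target SDs and means. Sample moments then equal the specification to
  machine precision for **any** seed, which is what makes printed-number
  tests possible. Whitening requires the centered draw to have full column
  rank, enforced as $n \ge m + 2$; a rank-deficient draw (probability zero,
  but guarded) is redrawn up to five times.
* At the original scale — 16 athletes, 17 variables — exact matching is
  rank-infeasible, so `generate_sampled()` draws i.i.d. rows from the
  implied multivariate normal instead; moments then converge at the usual
  $1/\sqrt{n}$ rate (checked at $n = 10^5$).
* The indicator–indicator correlations are not printed. They are completed
  rank-one, $r_{ij} = r_i r_j$, the structure implied by a single latent
  factor measured exactly by the criterion — the most parsimonious model
  consistent with the printed column, and always a valid correlation
  matrix when all $|r_i| < 1$. A `zero` completion (diagonal indicator
  block) is available; it can be indefinite under strong criterion
  correlations and is then repaired by clipping eigenvalues at $10^{-6}$,
  reconstructing, and rescaling to unit diagonal — adequate at dimension
  17, where a full nearest-correlation iteration would be overkill.
* Seeds are mandatory; both generators are pure functions of
  `(spec, n, seed)`.

What the generator does **not** emulate: non-Gaussian marginals (several
real indicators — counts, bounded scores, error magnitudes — are clearly
non-normal), measurement error, age structure, or the true
indicator–indicator dependence. Tests passing on synthetic cohorts
therefore validate the *computations* (moments imposed correctly, GRA and
factor algebra right), not the study's substantive conclusions on real
athletes.

## Problem sizes and numerics

The default analysis cohort is $n = 40$ (the smallest round size
comfortably above the $n \ge 19$ exact-matching floor for 17 variables,
and large enough for stable 16-indicator Pearson p-values). Factor-recovery
tests use $n = 200$–$500$ athletes with loadings of 0.7 and above; the
grey-relational brute-force cross-checks enumerate all cohort shapes up to
$5 \times 5$. Tolerances: imposed moments $10^{-8}$; eigenvalue-sum and
communality conservation $10^{-8}$; varimax versus grid search $10^{-6}$;
oracle equivalence for GRA $10^{-12}$.

## Limitations

* Grades inherit the global-extrema coupling described above: they are
  comparable within one table, not across tables with different indicator
  sets.
* The rank-one completion is a modeling choice, not a published fact; any
  quantity depending on indicator–indicator correlations (e.g. factor
  structure of synthetic cohorts) reflects that choice.
* Mean normalization requires positive-mean sequences; indicators that can
  straddle zero must be shifted or re-expressed by the user before
  analysis, and the package refuses rather than guessing.
* With published summary moments as the only anchor, the published grey
  relational grades themselves (computed from the undeposited raw data)
  cannot be recomputed, only the classification of their printed values.
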