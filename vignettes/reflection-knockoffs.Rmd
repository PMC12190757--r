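---
title: "Reflection knockoffs: model, construction, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reflection knockoffs: model, construction, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reko)
```

## The problem

In proteomics and genetic fine mapping, many features are strongly
correlated — proteins through shared regulation and assay cross-reactivity,
variants through linkage disequilibrium. A feature can then show a strong
marginal association with a phenotype purely by "hitchhiking" on a
correlated driver. The knockoff filter separates drivers from hitchhikers
with finite-sample false discovery rate (FDR) control: it builds a synthetic
copy $\tilde X$ of the feature matrix $X$ that preserves the correlation
structure but is, by construction, conditionally independent of the
phenotype, fits a joint model to $[X, \tilde X]$, and selects features whose
importance clearly exceeds that of their own knockoff.

The requirements on $\tilde X$ are second-moment conditions:
$\mathrm{cov}(\tilde X) = \Sigma$, $\mathrm{cov}(X_j, \tilde X_k) =
\Sigma_{jk}$ for $j \neq k$, and $\mathrm{cov}(X_j, \tilde X_j) =
\Sigma_{jj} - S_j$ for a diagonal $S \ge 0$ with $2S - S\Sigma^{-1}S \succeq
0$. Large $S$ means each knockoff is well decorrelated from its original —
that is where the filter's power comes from — so the craft of knockoff
construction is choosing $S$ as large as the constraint allows, stably.

## Reflection knockoffs

This package estimates $S$ through Householder reflection. For each
standardized feature $X_j$, regress it on the remaining features, and
reflect it through the fitted value: $Y_j = 2\hat X_j - X_j$. The
half-difference $Z = (X - Y)/2$ is exactly the stack of per-feature
regression residuals, so $Z_j$ is orthogonal to every other feature and
$T = \mathrm{cov}(X, Z)$ is diagonal with $T_{jj} = \mathrm{var}(Z_j) > 0$.
Setting $S = \alpha T$, the positive-semidefiniteness constraint reduces to
a one-dimensional condition on the spectrum of $C = \mathrm{cov}(Z
T^{-1/2})$: it suffices that $\alpha \le 2/\Lambda_1$, with $\Lambda_1$ the
leading eigenvalue of $C$. The package uses $\hat\alpha = \min(1,
2/\Lambda_1)$ and draws knockoffs as

$$\tilde X = X - \hat\alpha Z + U\,B(\hat\alpha)\,Q^\top T^{1/2}, \qquad
B^2(\alpha) = 2\alpha I - \alpha^2 \Lambda,$$

where $Q \Lambda Q^\top$ is the eigendecomposition of $C$ and $U$ carries the
fresh randomness. $C$ has unit diagonal, and its off-diagonal entries are
residual correlations $-r(r^2-1)/(1-r^2) \cdot$ (scale), which are small both
for weak and for very strong feature correlation — so $\Lambda_1$ stays near
1 and $\hat\alpha$ stays away from 0. No semidefinite program is needed, and
there is no optimizer to diverge: one eigendecomposition fixes everything.

Two noise modes are provided. The default draws the columns of $U$ i.i.d.
standard normal, so the second-moment conditions hold in expectation. The
`nullspace` mode instead takes orthonormal directions orthogonal to both the
feature columns and the intercept, rescaled to unit sample variance; the
joint sample covariance of $[X, \tilde X]$ then matches the block structure
*exactly*, which the test suite exploits at tolerance $10^{-6}$. Because the
intercept direction must be excluded for sample covariances to come out
exactly, this mode needs $n \ge 2p + 1$. The null-space basis itself is
arbitrary — any orthonormal choice yields a valid knockoff — and we document
that rather than fix a canonical basis.

A numerical tie-break worth stating: when $C$ is numerically diagonal (all
off-diagonal entries below $10^{-10}$, as with orthogonal features), the
coordinate basis is used as its eigenbasis instead of the dense eigensolver,
whose basis is arbitrary under repeated eigenvalues. With that convention
the uncorrelated special case degenerates exactly to $\tilde X = U$.

## Ghost samples and empirical-Bayes shrinkage

When features are highly correlated (or $p > n$), the residuals $Z_j$
collapse toward zero and the knockoffs lose power. The package regularizes
each per-feature regression with an independent Gaussian prior of variance
$\sigma_j^2$ on the coefficients, implemented by appending $p$ ghost rows
$\mathrm{diag}(1/\sigma_1, \dots, 1/\sigma_p)$ to $X$ before the QR
decomposition — the augmented least-squares solution is exactly the ridge
posterior mean. This keeps $T_j$ bounded away from zero and makes the
reflection well defined for any matrix shape. The fixed default
$\sigma_j^2 = 1/p$ is available, but the default path estimates each
$\sigma_j^2$ by empirical Bayes: the marginal likelihood of the
regression of $X_j$ on $X_{-j}$ is, after rotation into the eigenbasis of
the Gram matrix $X_{-j}X_{-j}^\top$ and profiling the residual precision,

$$\ell_j(\sigma^2) = -\tfrac{m}{2}\log \sum_i \frac{u_i^2}{\sigma^2 d_i + 1}
  - \tfrac12 \sum_i \log(\sigma^2 d_i + 1),$$

maximized by bisection of its derivative over $(10^{-6}, 1]$. The upper
bound 1 is a practical cap stabilizing the search; the lower bound and the
bisection tolerance ($10^{-8}$) are our declared choices. When the
derivative does not change sign the better endpoint is returned and flagged;
when the likelihood carries no information ($d \equiv 0$) the default $1/p$
is filled in, flagged as such. The residual precision is profiled
analytically (closed form) rather than estimated jointly.

Computing a fresh eigendecomposition per feature would cost $O(np^3)$.
Instead the eigenvectors of $XX^\top$ are shared across features and only
the eigenvalues are corrected: $X_{-j}X_{-j}^\top = XX^\top - x_j
x_j^\top$, a rank-one downdate whose eigenvalues are the roots of a secular
equation, bisected inside interlacing brackets (all roots vectorized
simultaneously). Because $x_j$ lies in the span of the eigenvectors of
$XX^\top$, the downdated eigen*values* are exact, and the rotated response
coordinates follow in closed form from the downdated eigenvector formula
$v_k \propto (\Lambda - \mu_k I)^{-1} z$ — so the `rank-one-update` mode
agrees with the dense `exact` mode to root-finding tolerance while costing
$O(np + p^2)$ per feature. For large matrices the `rsvd` mode replaces the
full SVD with a randomized range-finder keeping the top $k$ eigenpairs
(default $\min(200, n, p)$, oversampling 10, two power iterations); the part
of $x_j$ outside the retained eigenspace is assigned to a zero-eigenvalue
coordinate. This truncation is a genuine approximation: on matrices whose
spectrum does not decay within $k$ components the estimated priors can
differ noticeably from exact mode, which is why `rsvd` is reserved for
problems where the retained eigenpairs capture the spectrum.

## The filter, importance measures, and aggregation

Two importance measures are built in. The lasso measure fits
cross-validated `glmnet` on $[X, \tilde X]$ and uses absolute coefficients;
the columns are randomly interleaved (seeded) before fitting because the
coordinate-descent path is order-sensitive and a fixed original-then-knockoff
order would bias the null statistics. The Bayesian measure runs a
spike-and-slab Gibbs sampler (prior inclusion $1/p$, slab variance 1 on the
standardized phenotype, 2000 sweeps with 500 burn-in by default — declared
stand-in defaults, tunable) and uses posterior inclusion probabilities.
Single-site Gibbs cannot exchange inclusion between near-duplicate columns,
so after every sweep each included column is paired with a random partner
for a joint update of the two indicators with both coefficients integrated
out — an exact block-Gibbs move that restores model averaging across clones.

The knockoff statistic is $W_j = \mathrm{imp}_j - \mathrm{imp}_{\tilde j}$,
and the threshold is the usual data-dependent one over candidate values
$t \in \{|W_j| : W_j \neq 0\}$, with the `knockoff_plus` variant adding 1 to
the numerator (the variant carrying the exact finite-sample guarantee; the
plain variant is the default). Selection uses $W_j \ge T$; the aggregated
rule compares the per-feature average $\bar W_j$ against the threshold
computed from the concatenation of the $M$ statistic vectors. Ties at $T$
are measure-zero with continuous statistics, so the choice of $\ge$ over $>$
at the boundary is documentation, not substance. With $M = 1$ the
aggregated rule reduces exactly to the single-copy filter, and duplicated
copies change nothing — both are asserted in the tests. The aggregation rule
assumes that non-null features have positive statistics in every copy; for
weak signals this can fail, in which case averaging attenuates rather than
reinforces them. The combined filter intersects the lasso and PIP
selections, trading power for a realized FDR that is better calibrated when
both engines over-select in different ways.

## What the synthetic-data generator emulates

`gen_features` draws Gaussian features with independent, AR(1), or
equicorrelated-block structure; `gen_phenotype` draws standard-normal effect
sizes on a uniformly chosen causal set and sets the noise variance so the
proportion of variance explained (PVE) matches its target in expectation.
These reproduce the stylized designs used for method comparison — including
a dense strong-signal preset (200 causal features, PVE 0.90) mirroring
proteomic applications — but not the features of real data that make the
problem hard in practice: heavy-tailed or discrete (dosage) margins,
correlation blocks of irregular shape, linkage patterns with long-range
structure, or confounding that survives residualization. Passing tests on
these designs therefore demonstrates correctness of the machinery and FDR
control under the stated Gaussian designs, not performance guarantees on
arbitrary real matrices — the method itself comes with no theoretical FDR
guarantee under arbitrary covariance. `trim_features` implements the
practitioners' preprocessing step of capping pairwise correlation, removing
the weaker-associated (or a random) member of each offending pair, scanning
pairs in order of decreasing correlation (the greedy order is our choice;
any order yields a valid cap).

## Problem sizes and numerical choices

All sample covariances use the $n-1$ divisor on centered columns,
consistently. The benchmark harness pools true and false positives over
replicates (rather than averaging per-replicate rates), matching how
power and realized FDR are reported in the simulation studies this package
accompanies. Default problem sizes in the test suite are scaled for a
single CPU: the FDR-control check runs 40 replicates at $n = 500, p = 100$
with $M = 3$ copies, and the aggregation power comparison 15 replicates at
$n = 400, p = 80$ with $M = 10$ — both assert their guarantee within two
Monte-Carlo standard errors of the pooled counts. The acceptance script
(`scripts/acceptance.R`) runs the full design of record: $n = 800$,
$p = 150$, AR(1) $\rho = 0.5$, 20 causal features at PVE 0.5, $M = 3$,
knockoff-plus at $q = 0.10$, pooled over 100 replicates.

Other numeric tie-breaks: negative values of $2\hat\alpha -
\hat\alpha^2\Lambda_j$ (floating-point fuzz at the boundary) are clipped to
zero before the square root; the eigendecomposition of $C$ symmetrizes its
argument; secular roots whose rotated coordinate is negligible
($z_i^2 < 10^{-14}\,\Lambda_1$) are deflated and pass through unchanged;
a failed secular bracket falls back to a dense eigendecomposition with a
warning. Degenerate inputs are rejected rather than repaired: constant
columns, missing values, $p = 1$, rank-deficient unaugmented reflection,
zero-variance phenotypes.

## A worked example

```{r example}
X <- gen_features(300, 40, structure = list(kind = "ar1", rho = 0.6), seed = 1)
ph <- gen_phenotype(X, n_causal = 6, pve = 0.5, seed = 2)

fit <- reko(X)                # EB priors, rank-one-update mode
fit

kf <- knockoff_filter(X, ph$y, M = 5, q = 0.2, seed = 3)
kf
sort(ph$causal)
```

## Known limitations

The FDR guarantee inherited from the knockoff framework is exact for the
plus variant under valid knockoffs; the reflection construction matches
second moments (exactly in null-space mode) but, like other fixed-X-flavored
constructions, offers no theoretical control under arbitrary covariance —
empirically, realized FDR inflates when the largest correlations approach
0.99, and the combined filter is the recommended mitigation. The `rsvd`
prior mode is approximate in the stated way. The Gibbs sampler's pairwise
moves mix across pairs of clones; pathological cliques of many
interchangeable features may still mix slowly. File formats are plain
delimited text only; genotype containers (VCF/PLINK) are out of scope, as is
mixed-model pre-residualization — phenotypes and features should arrive
already residualized.
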