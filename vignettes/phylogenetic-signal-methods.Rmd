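---
title: "Models, statistics and design choices in pcmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, statistics and design choices in pcmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmkit)
```

# The problem this package addresses

Bacterial and archaeal genome sizes span roughly two orders of magnitude,
and many hypotheses — strength of purifying selection, effective population
size, ecological strategy — have been proposed to explain the variation.
Any regression that treats genera as independent data points ignores that
related lineages inherit similar trait values from common ancestors, which
inflates apparent associations. `pcmkit` provides the comparative machinery
needed to ask these questions properly on a genus-level phylogeny: does a
trait carry phylogenetic signal, which stochastic model of trait change
describes it best, and does a predictor survive once residual phylogenetic
covariance is modelled?

All analyses consume a rooted phylogeny with branch lengths in
substitutions per site and a tip-indexed trait table (genome size in Mbp,
median dN/dS, 16S rRNA copy number). Branch lengths are used exactly as
given — no rescaling to unit height — because the magnitudes of rate and
attraction parameters are only interpretable on the tree's own scale. The
tree is taken as non-ultrametric; nothing assumes a molecular clock.

# The Gaussian machinery

Every trait-evolution model here is a multivariate normal for the tip
vector $y$: mean $m(\theta)$ and covariance $\sigma^2 V(\theta)$. For fixed
$V$, the GLS mean $\hat\mu = (1^\top V^{-1}1)^{-1} 1^\top V^{-1} y$ and the
ML variance $\hat\sigma^2 = (y-\hat\mu)^\top V^{-1}(y-\hat\mu)/n$ are exact,
so only the covariance-shape parameters are searched numerically, each over
a bounded interval with a deterministic multi-start (interval subdivision
plus endpoint checks, convergence tolerance $10^{-8}$). ML is used
throughout, never REML, so log-likelihoods are comparable across models with
different fixed effects and valid in likelihood-ratio tests.

All solves go through a Cholesky factor of $V$; the log-determinant is
accumulated from the factor diagonal, which is stable at the target size of
836 taxa. If the factorization fails the fit errors — there is no silent
pseudo-inverse fallback, because a non-PD covariance always signals a
modelling or data problem (e.g. duplicated tips at zero distance).
Zero-length terminal branches are floored at $10^{-8}$ (configurable, and
logged) for the same reason.

## The model set

With $C$ the Brownian path-sum covariance ($C_{ij}$ = shared root-path
length), $h_i = C_{ii}$ the root-to-tip distances, and $d_{ij}$ patristic
distances:

* **Brownian motion** — $V = C$; closed form; $k = 2$ ($\sigma^2$, root
  state $z_0$).
* **White noise** — $V = I$; tips iid; the non-phylogenetic null; $k = 2$.
* **Pagel's lambda** — off-diagonals of $C$ multiplied by
  $\lambda \in [0, 1]$; $k = 3$. $\lambda = 1$ is BM, $\lambda = 0$ keeps
  only the tip variances.
* **Ornstein–Uhlenbeck** — attraction $\alpha > 0$ toward an optimum:
  $V_{ij} = \tfrac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
  (1 - e^{-2\alpha s_{ij}})$ with $s_{ij}$ the root-to-MRCA depth. This is
  the non-ultrametric form; it reduces to the familiar one at equal tip
  heights and to $\sigma^2 C$ as $\alpha \to 0$. The $\alpha \to 0$
  boundary is BM's job, so $\alpha$ is searched on a log axis from
  $10^{-6}$; the OU log-likelihood can therefore never fall below BM's by
  more than numerical noise.
* **Early-Burst** — rate $\sigma^2 e^{a t}$ with $a \le 0$;
  $V_{ij} = \sigma^2\,\mathrm{expm1}(a\,s_{ij})/a$. $a = 0$ collapses to BM
  and is reported with a boundary flag, not hidden. The lower bound is a
  fixed $a_{\min} = -10$ per unit branch length.
* **Trend diffusion** — rate $\sigma_0^2 + \beta t$ changing linearly with
  time from the root, constrained non-negative over the tree depth:
  $V_{ij} = \sigma_0^2 s_{ij} + \beta s_{ij}^2/2$. Fitted through the ratio
  $r = \beta/\sigma_0^2$ on a log-warped axis so the nested BM point
  ($r = 0$) is always resolved; the conventional $|\beta| \le 100$ bound is
  enforced inside the profile and flagged when hit.
* **Drift** — directional mean change on a non-clock tree:
  $E[y_i] = z_0 + \beta h_i$ with BM covariance. On an ultrametric tree all
  $h_i$ coincide and the drift coefficient is confounded with $z_0$; the
  fit then returns BM's likelihood with an explicit unidentifiability
  warning rather than an arbitrary coefficient.

Parameter counts (2 for BM/white, 3 for the rest) follow the AIC arithmetic
of the one-parameter extensions; `compare_models()` checks the fits share a
data vector, sorts by AIC and attaches likelihood-ratio tests against BM
for the models nested with it. White noise is not nested in BM on a
non-ultrametric tree and gets AIC ranking only.

# Signal statistics

**Blomberg's K** compares the observed ratio of the non-phylogenetic to the
phylogenetically corrected mean square of the trait around its GLS mean
with the ratio expected under BM,
$[\mathrm{tr}(C) - n/\mathbf{1}^\top C^{-1}\mathbf{1}]/(n-1)$, making
$K = 1$ the BM reference and $K$ free of trait location and scale (a tested
invariant). Significance comes from permuting trait values across tips:
the p-value is the share of permutations — observed configuration included
— whose corrected mean square is at most the observed one. The default of
999 permutations makes the smallest attainable p-value $1/1000$.

**Pagel's λ** is estimated by profile ML; its 95% interval is the set of
λ whose profile log-likelihood is within 1.92 ($\chi^2_1/2$ at 95%) of the
maximum, and LRTs against λ = 0 (no signal) and λ = 1 (BM) are reported.
The λ = 1 test is numerically identical to the BM-vs-lambda model
comparison — a cross-module consistency the suite asserts.

**κ and δ** are estimated marginally (the other transform held at 1): κ
exponentiates individual branch lengths (κ → 0 is a punctuational clock —
change per split, not per unit length), δ exponentiates node depths (δ > 1
concentrates change tipward). Both are optimized over the conventional
[0, 3] cap; an estimate pinned at a bound — the tipward-acceleration case
δ = 3 arises naturally on real data — is reported with an explicit
boundary flag instead of being presented as an interior optimum.

Per-group signal reports prune the tree to each group, require at least 4
tips, skip (and log) smaller groups, and flag groups under 25 tips, where
signal estimates are known to be unstable.

# Regression

`gls_fit()` is ordinary least squares reported with a Gaussian ML
log-likelihood (AIC-comparable with the phylogenetic fits) and Nagelkerke's
pseudo-R² against the intercept-only model. `pgls_fit()` builds the
residual covariance in the fixed composition order

> κ on branch lengths → path-sum C → δ element-wise → λ off-diagonal,

a choice that must be pinned down because the three transforms do not
commute and published tables report all three simultaneously. Requested
transforms are either fixed or jointly ML-estimated (bounded multi-start at
(1, 1, 1), (0.5, 0.5, 1.5), (0.24, 0.98, 2.5)); each ML transform gets a
95% profile-likelihood interval with the others re-optimized at every
profile point, and λ additionally gets "different from 0" / "different
from 1" LRT flags at α = 0.05. Coefficient tests are t-tests on $n - p$
degrees of freedom with the residual variance taken as RSS/(n − p); the
overall model p-value is an LRT against the intercept-only model under the
same transform treatment.

Two pseudo-R² variants are always computed, because conventions differ by
context: the whitened multiple R² (1 − RSS/TSS after premultiplying by the
inverse Cholesky factor of the fitted covariance; exactly 0 for the null
model) and Nagelkerke's likelihood-based R². `anova_nested()` compares
nested predictor sets by an F test on whitened residual sums of squares,
re-whitening the smaller model under the larger model's fitted covariance
so the two sums are commensurable, with an LRT cross-check.

# The dN/dS protocol

Pairwise dN/dS tables (the long format produced by ML estimators run in
pairwise mode) are filtered in the stated order: dS > 1.5 (synonymous-site
saturation), then dS < 0.1 (likely same-population pairs), then ω > 10
(artifacts). The inequalities are strict, so boundary values 0.1, 1.5 and
10 survive — the filter descriptions are written as strict and the package
treats that as contractual, with tests on the exact boundaries. The
minimum-support rule (a genome needs ≥ 25 surviving pairs) is applied once
rather than iterated after removals, since no re-checking is described;
per-genome pair counts are returned so the cascade is auditable. Support is
counted per genome, not per genus — the rule's subject is the genome.
Per-genus medians use the midpoint convention for even counts.

The bundled Nei–Gojobori (1986) counting estimator with Jukes–Cantor
correction exists so the pipeline is testable without external binaries; it
is not a substitute for an ML estimator on real data. Conventions: standard
genetic code only; ambiguity codes and gaps rejected; mutations to stop
codons count as nonsynonymous in the 1/3-fraction site counts; multi-hit
codons average over single-step pathways, excluding pathways that cross a
stop codon (falling back to all pathways if none survive); proportions at
or beyond the Jukes–Cantor limit of 3/4 raise a saturation error rather
than returning NaN.

Genome selection mirrors a taxonomy-database workflow: inclusive
completeness/contamination thresholds (≥ 95% / ≤ 5%; relaxed to ≥ 80%
completeness for CPR lineages), seeded downsampling of classes above 500
genomes, then removal of genus singletons — in that order, with per-rule
counts logged.

# The synthetic world

The generators state a world once and the tests live in it:

* **Trees** are Yule pure-birth, simulated forward from two root lineages;
  after the n-th lineage appears the process runs one further waiting time
  so pendant edges are positive. Depth is exactly
  $\sum_{k=2}^{n}\mathrm{Exp}(k b)$, which the suite checks against its
  closed-form mean. A multiplicative log-normal branch jitter (mean-one)
  emulates the roughness of substitutions-per-site trees; recovery tests
  use moderate jitter (sd 0.2–0.5).
* **Traits** are drawn from the exact model covariance through an
  eigenfactor (not Cholesky: strong Early-Burst parameters make recent
  splits numerically coincident, and the covariance is then only PSD).
* **Regression data** are $y = X\beta + \varepsilon$ with
  $\varepsilon \sim N(0, \sigma^2 C_\lambda)$ and iid or BM predictors.
* **Pairwise dN/dS tables** draw dS uniform on (0, 2.5] — spanning both dS
  thresholds so filter fractions are analytic — and ω log-normal with
  median 0.1 and log-sd 0.5, typical of purifying selection on conserved
  bacterial marker genes.
* **Codon pairs** differ by exactly the requested numbers of synonymous
  (fourfold third-position) and nonsynonymous (first-position, stop-safe)
  single-base changes at distinct codons.

What the generators do **not** emulate: horizontal transfer (trait jumps
decoupled from the tree), lineage-specific rate regimes, measurement error
in trait values, non-independence between dS and ω, or codon usage bias.
A green simulation test therefore establishes correctness of the estimators
under their own model assumptions — not robustness to violations of them.

# Numerical choices and edge cases

* Optimizer bounds: λ ∈ [0, 1] by default (extendable), κ and δ capped at
  3, OU's α searched on [10⁻⁶, 100] log-spaced, EB's a ∈ [−10, 0],
  trend/drift coefficients bounded at ±100. Estimates within tolerance of a
  bound are snapped to it and flagged.
* A basal polytomy is treated as a rooted polytomy (the stored basal node
  is the root); in Newick this case is indistinguishable from an "unrooted"
  tree, and path-sum covariance is well defined either way.
* Model fits accept n ≥ 2 (the two-tip BM fit has a hand-derivable closed
  form used as a test oracle); tree/trait alignment requires 3 overlapping
  tips before declaring anything fittable; Blomberg's K requires 4.
* Constant traits raise a degenerate-data error; exact-fit regressions
  (zero residual) return R² = 1 with zero standard errors instead of
  failing.
* Seeded functions snapshot and restore the caller's RNG state, so package
  calls never perturb user-level reproducibility.

# Known limitations

No measurement-error ("star-phylogeny inflation") models, no multi-rate or
multi-regime extensions, no phylogenetic logistic regression, and no
within-fit imputation of missing trait values (tips lacking a trait are
pruned, with logging). The κ/δ profile intervals assume the marginal
estimation design; joint κ–λ–δ uncertainty is available only through the
PGLS profile machinery. The NG86 estimator deliberately refuses saturated
alignments rather than extrapolating.
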