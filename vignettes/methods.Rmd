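---
title: "Models and methods behind mistkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mistkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mistkit)
```

mistkit measures misinformation susceptibility with balanced true/false
headline tests and provides the psychometric machinery used to build such
tests. This vignette documents the models, the defaults and why they are
set where they are, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The Verification-done scoring model

A bank presents k headlines, half real and half fake, and the respondent
labels each *real* or *fake*. Five quantities summarize a response vector:
`r` (real items labeled real), `f` (fake items labeled fake),
`V = r + f` (veracity discernment), and the judgment biases
`d = max(0, #fake-labels − k_fake)` (distrust) and
`n = max(0, #real-labels − k_real)` (naïveté). With no missing responses at
most one bias is positive, and on a balanced bank `d − n = f − r` — an
algebraic identity of any per-respondent counting definition. The bias
formulas are our documented reading of the framework's semantics
(over-labeling *fake* is over-skepticism); published summary statistics for
the biases in one field application are not exactly consistent with this
identity, which suggests they were computed on a different item set. We do
not bend the definition to match those summaries; `score_responses()`
documents the rule it applies.

Missing responses are an error by default. The permissive mode
(`allow_missing = TRUE`) scores answered items only and reports a prorated
`V`; it never imputes, because imputation on a 50%-guessable binary test
mostly manufactures information.

Norm tables map raw scores to population percentiles on a 0–100-by-5 grid.
`score_at_percentile()` is an exact table read (no interpolation — the
published tables are the instrument), and `percentile_rank()` inverts it
with ties resolved to the *largest* qualifying percentile, since the grids
repeat scores across adjacent percentiles.

## The item response model

All item-level modeling uses the three-parameter logistic,
$P(\theta) = c + (1-c)\,/\,(1 + e^{-a(\theta - b)})$, with the guessing
floor fixed at $c = 0.5$: a binary real/fake judgment is a two-alternative
task, so chance performance is 50%. The logistic metric is used without
the 1.702 normal-ogive constant, matching the convention of mainstream IRT
software; the conversion to factor loadings
($\lambda = (a/1.702)/\sqrt{1+(a/1.702)^2}$) reintroduces the constant
where the normal metric is the natural scale.

**EAP scoring** uses 61 equally spaced quadrature nodes on $[-6, 6]$ under
a standard-normal prior. At that resolution the posterior mean agrees with
a $10^5$-point dense-grid integration to better than $10^{-3}$, which is
far below the posterior SD of any realistic test length.

**Calibration** (`calibrate_3pl_em()`) maximizes the marginal likelihood by
EM over the same quadrature grid, with `a` and `b` free per item, `c`
fixed, and box constraints $a \in (0.05, 10]$, $b \in [-6, 6]$. No priors
are placed on `a`/`b`. Convergence is declared when the largest parameter
change falls below $10^{-4}$ or the marginal log-likelihood improves by
less than $10^{-6}$, up to 500 cycles; the log-likelihood trace is stored
and is non-decreasing (an EM invariant the tests assert). Items answered
identically by everyone are rejected, and samples under 200 respondents
draw a warning. Calibration is per-factor unidimensional: real-news and
fake-news items are calibrated separately, matching the two-factor design
of the instrument; the two information surfaces can be summed for a
descriptive full-test picture. Whether the original analyses calibrated
jointly or per-factor is not stated in the source material; we adopt
per-factor and do not claim equivalence.

A note on precision: with $c$ fixed at 0.5, half of every response is
guessing, and the discrimination of hard items is weakly identified. At
n = 2000 the Cramér–Rao bound for the ten-item recovery design used in our
tests already implies an RMSE for `a` around 0.24 *with the trait known*;
the realized marginal-ML RMSE is typically 0.3–0.7 depending on the data
seed, while `b` is recovered an order of magnitude more precisely. Users
calibrating their own banks should expect discrimination estimates to be
the noisy ones.

**DIF screening** (`dif_likelihood_ratio()`) tests, per item, group-specific
$(a, b)$ against shared values (df = 2) with every other item anchored at
the pooled calibration — the standard anchored-LR design. Flags are
uncorrected at $\alpha = .05$, as is conventional for screening; continuous
grouping variables (e.g. ideology) should be median-split by the caller.

## Classical test theory

**Tetrachoric correlations** are pairwise maximum likelihood: thresholds
fixed at the observed margins, and the latent correlation found by bounded
scalar search on the 2×2 table likelihood. Tables with an empty cell get a
+0.5 continuity correction on all cells. The bivariate-normal CDF inside
the likelihood is a Gauss–Legendre quadrature of the single-integral
(Drezner–Wesolowsky) form, panelled near $|\rho| \to 1$; it matches a
direct numerical-integration oracle to about $10^{-8}$. Non-positive-
definite matrices are eigen-clipped to a minimum eigenvalue of $10^{-6}$
and rescaled to unit diagonal, with a `smoothed` flag.

**Parallel analysis** compares observed tetrachoric eigenvalues with
per-rank 95th percentiles from 500 (by default) null datasets formed by
independent column permutations of the observed data. Permutation nulls
preserve the binary margins, keeping the null eigenvalues on the same
tetrachoric sampling scale — a Gaussian null would not be comparable. Some
published analyses quote a single common threshold rather than per-rank
thresholds; per-rank is the better-behaved convention and is what we
implement. Retention is the leading run of eigenvalues above threshold.
Because the margins are fixed under permutation, null tetrachorics are
memoized by their 2×2 cell count, which makes 500 replicates cheap.

**EFA** offers principal-axis factoring (communalities iterated from
squared multiple correlations, tolerance $10^{-3}$, 100 iterations) and
unweighted least squares (direct minimization over uniquenesses). Varimax
uses Kaiser normalization via `stats::varimax` and leaves communalities
unchanged; Heywood cases are clipped to 1 with a flag.

**Reliability.** Alpha is the covariance formula (KR-20 on binary items),
and `alpha_if_deleted_prune()` removes one item per iteration only when
deletion raises alpha by more than 0.001 — never an item whose deletion
lowers it. The omega report fits a two-factor congeneric model with the
assignment supplied by the user: within-factor loadings by one-factor PAF
per block, the inter-factor correlation $\phi$ from the cross-block
correlations, and a Schmid–Leiman style split $g_i = \lambda_i\sqrt\phi$,
$s_i = \lambda_i\sqrt{1-\phi}$, giving
$\omega_g = (\sum g_i)^2 / \sum_{ij} R_{ij}$ and per-facet omegas on each
block. On simulated orthogonal bifactor data this recovers the closed-form
general saturation of the generating model to within 0.05. The correlation
scale is selectable: Pearson on the observed 0/1 items (default) or
tetrachoric for the latent scale; exact omega recipes vary across software,
so ordering and range properties — not any particular published decimal —
are what the tests pin down. Item-total correlations are corrected (item
excluded from the total), a detail the source material leaves unspecified.

## Exploratory graph analysis

`estimate_network()` runs the graphical lasso (block coordinate descent,
written in-package since no glasso solver ships with the supported
environment) over 100 log-spaced penalties from the largest absolute
off-diagonal correlation down to 1% of it, scoring each solution with
$EBIC = -2\ell + E\log n + 4\gamma E \log p$ and returning the minimizer as
a partial-correlation network. $\gamma = 0.5$ is the conventional
sparsity-leaning default. At zero penalty the solver reduces exactly to
the inverse-correlation conversion, a limit the tests assert; at positive
penalties the solution satisfies the KKT conditions of the penalized
problem to $10^{-6}$.

Communities come from Walktrap on the graph weighted by absolute partial
correlations, with the customary 4-step walks (the source material does
not state a value). Singleton communities are merged into the community
with the greatest summed connection strength; a node with no edges keeps
its own dimension. **Network loadings** split each node's strength across
dimensions and standardize each dimension's column by the square root of
its members' summed within-dimension strength, restoring the dominant edge
sign. On simulated factor data with loadings .40/.55/.70 the standardized
network loadings land near the published anchor values .15/.25/.35, which
is the calibration the tests check. **Unique variable analysis** flags
pairs with weighted topological overlap ≥ 0.25 (the source method's
recommended cut) and suggests keeping the item with the higher ratio of
main loading to mean absolute cross-loading.

**bootEGA** is a parametric bootstrap: multivariate-normal replicates from
the smoothed empirical correlation matrix, re-estimated with Pearson
correlations. Replicates are continuous even when the data are binary —
re-dichotomizing and re-estimating tetrachorics per replicate would
multiply the cost for little change in the stability ranking, and the
source material does not state which was used; this simplification is
deliberate and documented. Replicate dimensions are aligned to the
empirical partition by maximal Jaccard overlap (ties: larger intersection,
then lower label). Item stability is the proportion of replicates placing
an item with its empirical dimension; structural consistency is the
proportion reproducing a dimension's item set exactly.

**TEFI** uses Von Neumann entropies of trace-normalized absolute
correlation (sub)matrices: with total entropy $H$, per-dimension entropies
$H_i$ and $K$ dimensions,
$TEFI = (\bar H_i - H) + (H - \sum_i H_i)\sqrt K$; lower is better. The
tests verify label-invariance, an eigenvalue-entropy oracle, and that the
true partition of a block structure beats merged alternatives — the
relative-fit behavior that makes the index useful.

## The item-selection decision tree

`run_decision_tree()` applies, in order: (1) iterated two-factor EFA
removal of items whose best loading is under .40 (simultaneous removal
within an iteration, refit until stable); (2) the same iteration for
cross-loadings over .30; (3) per-veracity-class 3PL calibration and
removal of items with implied communality under .40; (4) alpha pruning at
$\Delta\alpha > .001$; (5) an optional DIF screen where an item flagged
under *any* supplied grouping is removed. The full tetrachoric matrix is
computed once — it is pairwise, so every stage reuses the relevant
submatrix.

The final selection formalizes "high discrimination over a wide range of
difficulties," which the source material states as an aim without an
algorithm: eligible items ($a \ge a_{\min}$) are placed in `n_per_factor`
equal-width difficulty bins spanning the pooled `b` range, and the
highest-`a` item per bin is taken greedily, falling back to the nearest
unused eligible item for empty bins. This is a documented reconstruction,
not a claim about how the published scale was assembled. Content/topic
diversity is intentionally not automated; the result carries a manual
checklist instead.

## What the simulator emulates — and what it does not

`simulate_responses()` draws respondents from the measurement model the
scales are built on: a general discernment trait $\theta_V \sim N(0,1)$
with first-order traits
$\theta_r = \gamma_r \theta_V + \sqrt{1-\gamma_r^2}\,\varepsilon$ (and
likewise $\theta_f$), and item responses from the 3PL with the bank's
parameters. The default $\gamma_r = \gamma_f = 0.8$ encodes strongly
related but distinct detection abilities — the regime the two-factor
higher-order design presumes; $\gamma = 1$ collapses to one trait and
$\gamma = 0$ to independent ones, both useful for boundary tests. A bias
mixture overlays yea/nay-saying: with probability `bias_tau` a response is
bias-driven, labeled *fake* with probability `bias_pi`. Bias operates per
response by default so intermediate `d`/`n` values arise; a
per-respondent mode exists behind `bias_level = "respondent"`.
`simulate_item_pool()` plants factor structure, junk, cross-loaders and
redundant pairs by thresholding a linear factor model, with thresholds
drawn from ±0.8 and good loadings from [.55, .80] — latent-scale analogues
of the published difficulty and discrimination spreads.

What passing tests on these data show is that the pipeline recovers known
structure under its own generating assumptions. Real respondent data
violate those assumptions in ways the generator does not emulate: no
local dependence beyond the planted pairs, no careless or speeded
responding, no differential item functioning unless planted, no panel
demographics, and bias that is independent of the trait. Results on
synthetic data bound what the methods can do, not what any field sample
will look like.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything at fixed,
moderate sizes chosen to make the checks sharp without waste: $10^4$
random vectors for the scoring identities, n = 2000 for calibration
recovery, n = $10^4$ for tetrachoric recovery, 500 permutation nulls for
parallel analysis, 100 parametric bootstrap replicates for bootEGA (the
stability metrics are proportions; 100 replicates resolve them to 0.01),
20 seeds for the selection pipeline and the intervention dissociation.
Every stochastic step is seeded, and `scripts/acceptance.R` threads one
`--seed` through all of them.

## Known limitations

- Multidimensional IRT is out of scope: calibration is per-factor
  unidimensional, and the full-test information surface is a descriptive
  sum. 1PL/2PL/graded models are not offered.
- CFA/SEM fit indices (CFI/RMSEA/SRMR) are not computed; TEFI and the
  bootstrap stability metrics are the model-comparison tools here, and SEM
  software should be used where covariance-structure tests are needed.
- Tetrachorics assume an underlying bivariate normal; strongly skewed
  margins with small n make them unstable (the continuity correction
  mitigates, not removes, this).
- The omega decomposition presumes the two-facet structure it is given;
  it is not an exploratory bifactor fit.
- Hierarchical EGA variants and EGA-based invariance permutation tests are
  not implemented.
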