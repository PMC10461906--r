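---
title: "Models, unit trees, and adequacy testing: methods behind expadequacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, unit trees, and adequacy testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expadequacy)
```

## The problem

Comparative studies of gene expression ask how transcript abundance evolves
across species: whether it drifts freely, is held near an optimum by
stabilising selection, or diversified early and then slowed. The standard
workflow fits stochastic models of continuous trait evolution to each gene's
species-level expression on a time-calibrated phylogeny and compares them by
information criteria. Relative fit, however, says nothing about whether the
winning model describes the data *well*: the best of three bad models is
still a bad model. `expadequacy` implements both tiers for expression data —
relative fit by AIC, and absolute fit (adequacy) by parametric bootstrap on
a rescaled "unit tree".

## The three processes

All three models treat the log-scale species mean as a Gaussian process
along the tree, so each is fully specified by a mean and a covariance over
tips. With `t_shared(i, j)` the shared evolutionary history of two tips on
an ultrametric tree of depth `T`:

* **Brownian motion (BM).** Increments `dz = sigma dW`; the trait variance
  grows linearly at rate `sigma^2` (units: squared log-expression per unit
  time). `cov(i, j) = sigma^2 t_shared`. Free parameters: `sigma2`, root
  state `z0`.
* **Ornstein–Uhlenbeck (OU).** BM plus a restoring pull of strength `alpha`
  (per unit time) toward an optimum `theta`:
  `dz = -alpha (z - theta) + sigma dW`. With the root at the optimum,
  `cov(i, j) = sigma^2/(2 alpha) * exp(-2 alpha (T - t_shared)) *
  (1 - exp(-2 alpha t_shared))`; tip variance saturates at
  `sigma^2 / (2 alpha)`. Free parameters: `sigma2`, `alpha`, `theta`.
* **Early Burst (EB).** BM whose rate decays exponentially,
  `sigma^2(t) = sigma2 * exp(-r t)`; integrating the rate along shared
  history gives `cov(i, j) = sigma2 (1 - exp(-r t_shared)) / r`, with the
  BM limit as `r -> 0`. Free parameters: `sigma2` (initial rate), `r`,
  `z0`.

The root state is fixed at the OU optimum (`z0 = theta`), the standard
choice for ultrametric comparative fits; OU therefore has three free
parameters, the same count as EB. Measurement error — the standard error of
each species' mean log expression — enters as a *fixed* additive variance
`se^2` on the covariance diagonal. It is never estimated: with few
replicates per species a free error variance is barely identifiable and
absorbs genuine evolutionary signal.

Because OU at `alpha = 0` and EB at `r = 0` are exactly BM, the maximised
OU and EB log-likelihoods can never fall below BM's. The package treats
this nesting as an invariant and the test suite asserts it on every fitted
gene.

## Maximum-likelihood fitting

Each fit reduces to a one-dimensional problem. Conditional on the shape
parameter (`alpha` or `r`; BM has none), the mean (`z0` or `theta`) is
profiled analytically by GLS. When all standard errors are zero the rate
`sigma2` also profiles analytically (the GLS residual quadratic form over
`n`); with fixed `se^2` on the diagonal that profile is no longer closed
form and an inner one-dimensional optimisation on `log(sigma2)` is used
instead. The outer search evaluates the profile likelihood on a
deterministic 17-point logarithmic grid over the bounded shape range and
then refines with Brent's method inside the bracketing sub-interval. A
grid-plus-bracket scan is as robust as random multi-start for a
one-dimensional, typically unimodal profile, and it is exactly reproducible.

Bounds and numerical floors:

* `alpha` in `[1e-8, 50 / depth]`. At `alpha * depth = 50` the process has
  lost essentially all phylogenetic signal; larger values change the
  likelihood by less than machine precision.
* `r` in `[0, 20 / depth]`, with `r = 0` (exact BM) always evaluated.
* `sigma2` floored at `1e-12`; constant-trait genes hit this floor and the
  fit is flagged `sigma2_floor` rather than erroring.
* Estimates within 0.1% of a shape bound are flagged (`alpha_upper`,
  `r_upper`). Boundary fits are retained, not discarded.

Model choice uses plain AIC (`2k - 2 logLik`), not AICc, matching common
practice for these fits; with the small `n` typical of comparative
expression data the difference can matter and is deliberately left to the
user to weigh. Exact AIC ties are broken deterministically: fewer
parameters first, then the fixed order BM, OU, EB.

## Unit-tree rescaling and the five statistics

If the fitted model with its estimated parameters is the generating
process, rescaling every branch by the model-implied variance accumulated
along it turns the data into BM with rate 1. An edge from height `t1` to
`t2` becomes

* BM: `sigma2 (t2 - t1)`
* OU: `sigma2/(2 alpha) * (exp(-2 alpha (T - t2)) - exp(-2 alpha (T - t1)))`
* EB: `sigma2 (exp(-r t1) - exp(-r t2)) / r`

and each terminal edge gains the tip's `se^2`. (The OU and EB expressions
are evaluated via `expm1` so that vanishing shape parameters reproduce the
BM rescaling to near machine precision rather than to the ~1e-4 relative
error naive exponentials give.) On the unit tree the phylogenetic
independent contrasts (PICs) of adequate data are i.i.d. standard normal.
Five summary statistics probe different failures of that prediction:

| statistic | definition | sensitive to |
|---|---|---|
| `c.var` | coefficient of variation of |PIC| | unmodelled rate heterogeneity |
| `d.cdf` | KS distance of PICs from N(0,1) | non-normality, jumps |
| `s.asr` | OLS slope of |PIC| on ancestral state estimates | rate–state dependence |
| `s.hgt` | OLS slope of |PIC| on node heights (node-height test) | temporal rate trends |
| `s.var` | OLS slope of |PIC| on contrast variances | branch-length error |

`s.var` regresses on the expected variances themselves, not their square
roots. Observed statistics are computed on the same unit tree used for the
null simulations — this is what makes the N(0,1) reference valid — and the
null distributions come from `n_sim` BM(1) simulations on that unit tree
(default 1000; the simulation is an exact covariance draw propagated along
edges and all replicates are pushed through a vectorised contrast
recursion at once).

Two-tailed Monte Carlo p-values use the positively biased (conservative)
pseudo-count convention `p = 2 min[(1 + #{sim <= obs}) / (S + 1),
(1 + #{sim >= obs}) / (S + 1)]`, capped at 1, so p-values are never
exactly zero. No multiple-testing correction is applied across the five
statistics or across genes: a single hypothesis is tested per gene (the
data were generated by the fitted model), and a gene is called inadequate
when *any* statistic falls below the cutoff (default 0.05).

### The node-height degeneracy

When an OU fit drives `alpha` very large the unit tree puts almost all its
length on the terminal edges; internal node heights collapse toward a
point and a slope over them is not estimable. `s.hgt` is reported as `NA`
when the variance of unit-tree node heights falls below
`1e-6 * depth^2` — a relative threshold, so it is invariant to the overall
scale of the fitted rate. Its p-value and flag are then `NA` and the gene's
adequacy call uses the remaining four statistics. Genes in this regime have
low phylogenetic signal, which can be confirmed with `blomberg_k()`
(expectation 1 under BM; near 0 for phylogeny-free noise).

## Degenerate inputs and other numerical choices

* Polytomies are resolved deterministically (left-to-right) into
  zero-length bifurcations on input; before the contrast recursion,
  zero-length branches are floored at `1e-8 * depth` to keep divisions
  defined. Node heights are taken from the actual (unfloored) lengths.
* Ultrametricity is checked with a relative tolerance of `1e-3` of the
  depth by default, absorbing chronogram rounding noise.
* A constant trait across species cannot be fitted meaningfully: the rate
  floors at `1e-12` and the fit is flagged.
* Species missing a gene's data are excised from the tree for that gene
  only (branch lengths of collapsed degree-2 nodes are summed, so retained
  depths are unchanged). Genes with fewer than `min_taxa = 4` species are
  reported as skipped, never silently dropped: three contrasts is the
  minimum for any of the regression statistics.
* Species summarised from a single replicate get `se = 0` and are flagged
  rather than excluded.
* Expression is log-transformed as `log(x + offset)` with `offset = 1` by
  default; base and pseudo-count are configurable and must match between
  generation and analysis for round-trip tests.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces the full input bundle the pipeline reads: a
unit-depth pure-birth tree, a genes x (species x replicates) linear-scale
matrix with a sample sidecar, and a truth table. Per gene it draws a model
from `model_mix` (defaults: 40% BM, 40% OU, 10% EB, 10% rate-shift),
simulates species means on the tree, adds i.i.d. Gaussian noise on the log
scale to make replicates (default sd 0.3, three replicates — standard
errors of realistic magnitude for bulk RNA-seq species means), blanks a
configurable fraction of species per gene (default 10%), and
back-transforms with `pmax(exp(x) - offset, 0)`. Rate-shift genes run BM
at `sigma2 * multiplier` inside one fixed clade (stem edge included) and
are labelled `none` in the truth table: they violate all three fitted
models, emulating the unmodelled rate heterogeneity that drives `c.var`
and `s.asr` failures, and no multi-rate model is ever fitted to them.
Parameter ranges (rates 0.1–2 per unit depth, `alpha * depth` and
`r * depth` 0.5–4, root states 1–6 on the log scale) are chosen to span
weak-to-strong signal on a unit-depth tree, not calibrated to any
particular empirical dataset.

The generator deliberately does **not** emulate sequencing-depth (count)
noise, normalisation artifacts, gene-tree/species-tree discordance, or
correlated errors across genes. Tests passing on these data therefore
demonstrate the statistical machinery — calibration of the null, power
against rate shifts, parameter recovery — not robustness to every failure
mode of real RNA-seq pipelines.

## Problem sizes used in the tests

The suite's dataset-scale checks use sizes chosen to make their Monte
Carlo tolerances meaningful on a single CPU: null calibration and the
unit-tree BM(1) property use 1000 genes on a 64-tip tree with 500
bootstrap replicates each (per-statistic rejection rates must land in
[0.03, 0.07] at the 0.05 cutoff); OU parameter recovery uses 200 genes on
100 tips (`alpha * depth = 2`); rate-shift power uses 200 genes with a
25-fold shift on half of a 64-tip tree. Smaller deterministic fixtures
cover the closed-form examples.

## Known limitations

* Single-optimum, single-rate models only; fitting multi-regime OU or
  multi-rate BM is out of scope (rate-shift data are generated, but only
  as violations).
* The OU mean fixes the root at the optimum; ancestral-state displacement
  from `theta` is not modelled.
* ML fitting only — no REML rate estimates (except inside the contrast
  identity used by the tests) and no Bayesian/posterior-predictive mode.
* AIC on small species samples favours simple models; with fewer than ~10
  species OU support should be read cautiously.
* Adequacy p-values are conditional on the estimated parameters; parameter
  uncertainty is not propagated into the bootstrap.
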