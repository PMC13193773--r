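---
title: "Bayesian threshold animal models for parity-specific abortion traits"
author: "caprigen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian threshold animal models for parity-specific abortion traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprigen)
```

## The problem

Abortion in a dairy-goat herd is recorded per doe and parity as a binary
outcome.  Treating the outcome at each of the first three parities as a
distinct trait, the package estimates how much of the variation is
additive-genetic (heritability on the liability scale), how strongly the
three parity traits are genetically and phenotypically correlated, which
herd-level factors (year, season, doe age) shift the odds of abortion, and
which of four model variants — linear or threshold, univariate or
multivariate — predicts held-out records best.

## The liability (threshold) animal model

Each binary outcome is modelled through a latent Gaussian liability

$$ l = \mathbf{x}'\mathbf{b} + a + e, \qquad y = \mathbf{1}\{l > 0\}, $$

with fixed effects $\mathbf{b}$ (year, season, age class), an additive
genetic effect $a$ for every pedigree animal with
$\mathbf{a} \sim N(0, \mathbf{A} \otimes \mathbf{G}_0)$, where
$\mathbf{A}$ is the numerator relationship matrix, and residuals
$\mathbf{e}_d \sim N(0, \mathbf{R}_0)$ per doe across her parities.  Two
constraints make the binary model identifiable: the threshold is fixed at
0 and each threshold trait's residual variance at 1.  Heritability on the
liability scale is $h^2_t = g_{tt}/(g_{tt} + r_{tt})$; genetic and
phenotypic correlations are derived per MCMC draw and then summarized —
never as ratios of posterior means, because the two estimators genuinely
differ for skewed variance draws (this is pinned by a regression test).

In "linear" mode the same machinery treats the 0/1 outcome as a Gaussian
response; this deliberately misspecified variant exists because it is one
of the four compared models.

## Sampling scheme

The Gibbs sampler sweeps, in a fixed documented order: latent liabilities
(truncated-normal draws, with missing parities augmented untruncated from
their Gaussian conditional), fixed effects (scalar draws, flat priors),
breeding values (scalar draws in pedigree order using the sparse
$\mathbf{A}^{-1}$), the genetic covariance, and the residual covariance.
Every draw after the burn-in at the thinning interval is retained; the
published protocol of 200,000 iterations, 20,000 burn-in and thinning 100
retains exactly 1,800 draws and is the package default.

Three choices here were forced by numerical behaviour observed during
development, and are worth recording:

* **Residual covariance for threshold traits.**  A draw-then-rescale
  update (draw $\mathbf{R}_0$ from its unconstrained inverse-Wishart
  conditional, then rescale the state to unit diagonal) is *not* a valid
  Markov kernel for the constrained posterior: in experiments it drove
  the genetic variance to zero geometrically at a rate of roughly $5/n$
  per iteration.  A soft anchor (running the chain on an unidentified
  working scale with a proper residual prior) fails differently: flat
  priors on $p$ fixed-effect columns make the working scale drift upward
  like $c^{p}$ against only polynomial restraint, crushing the identified
  genetic variance — the more fixed-effect columns, the faster the
  collapse.  The implementation therefore keeps the chain on the
  identified scale exactly: threshold-trait residual variances are held
  at 1 and each residual *correlation* is drawn by griddy Gibbs — its
  full conditional evaluated on a 201-point grid restricted to the
  positive-definite region, under a uniform prior over feasible
  correlations.  For a single threshold trait the residual variance is
  simply fixed at 1.

* **Genetic covariance parameterization.**  The conjugate (centered)
  inverse-Wishart update $\mathbf{G}_0 \mid \mathbf{a} \sim
  IW(\nu_a + q,\; \mathbf{S}_a + \mathbf{a}'\mathbf{A}^{-1}\mathbf{a})$
  is implemented and unit-tested against its scaled inverse-chi-square
  closed form, and is the default for linear models.  For threshold
  models at realistic herd sizes (thousands of pedigree animals, binary
  records on a subset) it mixes pathologically near zero: once
  $\mathbf{G}_0$ fluctuates small, the breeding values shrink, the
  quadratic form shrinks, and escape takes far longer than any practical
  chain.  Threshold models therefore default to a non-centered
  parameterization: $\mathbf{a}_i = \boldsymbol\Lambda
  \tilde{\mathbf{a}}_i$ with standardized effects
  $\tilde{\mathbf{a}} \sim N(0, \mathbf{A} \otimes \mathbf{I})$ and the
  free elements of the genetic Cholesky factor $\boldsymbol\Lambda$
  updated by scalar Gibbs like regression coefficients.  This is the
  standard remedy for weakly informative hierarchical scales and mixes
  well precisely where the centered sampler sticks.  Each iteration ends
  with an interweaving move: holding the natural-scale breeding values
  fixed, the Cholesky factor is redrawn from its centered conditional by
  a Metropolis step with an inverse-Wishart proposal whose likelihood
  terms cancel exactly, so the chain gets the complementary mixing
  behaviour of both parameterizations.  The combined sampler was
  validated against an independent dense R implementation of the same
  model on a small dataset.

* **Priors.**  Linear models keep flat-equivalent variance priors.  For
  threshold models the elements of row $u$ of $\boldsymbol\Lambda$ are
  $N(0, 0.5/u)$, so every trait's genetic variance has the same prior
  scale 0.5 regardless of trait ordering (a naive constant element
  variance would give later traits systematically larger prior genetic
  variance).  This is weak over the liability heritabilities reported
  for binary fitness traits (prior median $h^2 \approx 0.19$, ample mass
  up to $\approx 0.5$) while proper, which the identified threshold
  posterior needs.  The centered threshold option uses a proper
  inverse-Wishart ($\nu_a = k + 2$, $\mathbf{S}_a = 0.2\,\mathbf{I}$)
  for the same reason.

Missing parities of a recorded doe are never dropped: their liabilities
are augmented untruncated, with no fixed-effect contribution, which
leaves the observed-data posterior untouched while keeping every doe's
residual vector complete.

## Pedigree algebra

Inbreeding coefficients use the Meuwissen–Luo indirect method;
$\mathbf{A}$ is built by the tabular recursion (dense, guarded at 5,000
animals); $\mathbf{A}^{-1}$ is assembled sparsely from Henderson's rules
with Mendelian-sampling variances that account for parental inbreeding,
$d_i = 0.5 - 0.25(F_s + F_d)$.  Two independent algorithms must agree:
`diag(A) - 1` equals the Meuwissen–Luo coefficients exactly, and
$\mathbf{A}^{-1}\mathbf{A} = \mathbf{I}$ to 1e-8 on random inbred
pedigrees — both are property-tested.

## The synthetic herd

No herd data ship with the package; the generator emulates the study
system end-to-end so every stage is testable.  Defaults describe an
intensively managed herd: about 3,400 unrelated founders expanded over
four offspring generations to roughly 35,000 animals; matings organised
in harems of 15 does per buck with partial buck carry-over between
generations; harems clustered by the does' paternal families, and a
small fraction (7%) of harems served by a paternal half-sib buck, which
yields a realistic share of inbred animals (the package reports the
realized fraction rather than asserting it).  About 3,974 does receive
parity-1 records, with nested retention probabilities (1, 0.817, 0.596)
reproducing the declining parity counts 3,974/3,247/2,370; a doe recorded
at parity $t$ is recorded at all earlier parities, as in a culling
process.

Liability-scale truth values are $h^2 = (0.25, 0.11, 0.19)$, genetic
correlations $(0.23, 0.29, 0.48)$ and phenotypic correlations
$(0.09, -0.07, 0.14)$, with unit residual diagonals; per-trait thresholds
are calibrated by bisection so expected incidences match
$(0.15, 0.18, 0.15)$.  Fixed effects on the liability scale are herd-book
plausible: year effects spanning about 0.35 liability SD, a protective
cold-season effect of $-0.12$, and age effects $(0, -0.45, -0.60,
-0.65)$ whose probit magnitudes mirror odds ratios of roughly 0.4–0.8.  A
doe's first parity falls in a uniformly drawn year and later parities
advance the year and the age class deterministically, so each parity sees
a shifted age range (1–2, 2–3, 3–4 years) and a shifted year range —
which is why the risk-factor reports use parity-specific reference
levels.  Year and season proportions are uniform because the study
distribution is not reported; both are configurable.

What the generator does *not* emulate: infectious abortion outbreaks
(which would cluster events within year-season cells beyond the
liability model), selection across generations, litter size or
production traits, and any non-additive genetic variance.  Recovery tests
on this generator therefore show that the estimation machinery is
correct under its own assumptions — not that real abortion data satisfy
those assumptions.

## Model comparison and risk factors

Cross-validation is stratified by doe (all parities of a doe share a
fold), with the same folds reused by all four model variants and chain
seeds derived from fold and variant content so identical variants
reproduce identical results.  Held-out does are predicted from training
posterior means: fixed effects by level lookup (unseen levels contribute
zero with a warning) and breeding values by parent average
$0.5(\hat a_s + \hat a_d)$.  Threshold predictions are abortion
probabilities $\Phi(\mathbf{x}'\hat{\mathbf{b}} + \hat a)$ — the latent
index would correlate identically, but the probability is the natural
scale against a binary observable.  Per-fold Pearson correlations are
averaged; the reported p-value is a one-sample t-test on Fisher-z
transformed per-fold correlations.  Because the study's description
mixes "five-fold" language with an equal-split design, `k` is
configurable and `k = 2` reproduces the equal-split reading; 5 is the
default.

Risk factors are analysed one trait at a time by maximum-likelihood
logistic regression with all three factors included together, odds
ratios with Wald intervals, and per-factor joint Wald tests (a
likelihood-ratio variant is available and is the automatic fallback for
singular sub-covariances).  The event modelled is abortion = 1.  The
logit link is used throughout: odds-ratio reporting presumes it, even
where a log link might be read into the model formula.  Reduced chains
(20,000/2,000/20) are the cross-validation default to keep 4 variants
times 5 folds tractable; full-protocol chains are a configuration switch.

## Problem sizes used by the test-suite

The automated checks run, as their standard configuration: parameter
recovery on five replicate herds of ~3,000 recorded does over three
generations with 20,000-iteration chains; model ranking on five replicate
herds of ~900 does with 3,000-iteration cross-validation chains; the
distributional (Kolmogorov–Smirnov) checks on 10,000 thinned draws; and
the pedigree-algebra suite on fifty random pedigrees of up to 200
animals.  These sizes were chosen so that each check has enough
resolution to detect the failure it guards against while the whole suite
stays convenient to run routinely.

Two properties of these conditions are worth knowing before reading the
automated results.  First, parameter recovery at ~3,000 binary records is
intrinsically marginal against a ±0.08 band: even when the *latent*
liabilities are handed to a linear model, replicate-level posterior means
miss the generating heritabilities by up to 0.08, because a herd founded
by a finite set of lineages realizes its own family-level genetic
variance; the binary scale roughly doubles that dispersion.  Second, the
four compared model variants genuinely differ by only ~0.01 in mean
cross-validated correlation under this generative model — held-out does
are predictable only through fixed effects and parent-average breeding
values — so their ranking is unstable at desk scale, and a large
separation between threshold-multivariate and linear-univariate
predictive ability is not something the liability model's own
assumptions can produce.

## Known limitations

* Single-chain diagnostics only (posterior SD, HPD, ESS by Geyer's
  initial positive sequence, trace plots); no multi-chain convergence
  statistics.
* Heritabilities are reported on the liability scale only; no
  observed-scale transformation.
* No maternal, permanent-environment, dominance or genomic effects; no
  unknown-parent groups.
* The mean inbreeding coefficient among inbred animals in the synthetic
  herd runs higher than typical herd-book values, because the related
  matings that generate inbreeding are half-sib matings; the *fraction*
  inbred is realistic, the depth profile of inbreeding is not.
* The Wald/LRT machinery assumes standard asymptotics; complete
  separation is detected and reported, not penalised away.
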