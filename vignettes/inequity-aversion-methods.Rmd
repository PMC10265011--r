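---
title: "Estimating inequity aversion from economic games: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating inequity aversion from economic games: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iafit)
```

## The model

iafit estimates social preferences from choices in five canonical economic
games — dictator (DG), prisoner's dilemma (PDG), public goods (PGG), trust
(TG) and ultimatum (UG) — using the Fehr–Schmidt inequity-aversion utility.
For an allocation giving `x` to the chooser and `y` to the other player,

U(x, y) = x − α · max((x + y)/2 − x, 0) − β · max(x − (x + y)/2, 0).

α (disadvantageous inequity aversion, DIA) penalizes falling short of the
equal split; β (advantageous inequity aversion, AIA) penalizes exceeding it.
At most one penalty is active. Choices among the options of a decision
context follow a softmax rule with inverse temperature λ,

P(option) = exp(λ U) / Σ exp(λ U),

so λ = 0 is random choice and large λ approaches deterministic utility
maximization. Each participant contributes 37 decisions (7 DG endowments; 1
each of PDG, PGG, TG-truster, UG-proposer; 10 TG-trustee and 16 UG-responder
strategy-method decisions), and (α, β, λ) are estimated per participant by
Bayesian MCMC over the joint likelihood of all 37 choices, treated as
conditionally independent given the parameters.

### Payoff scale

Payoffs are stored in JPY but divided by 1000 (kJPY) before entering the
utility, so a single λ of order 1–10 is comparable across games whose
stakes span JPY 0–3000. The divisor is the exported constant
`payoff_scale`.

### Beliefs about co-players

In the PDG, PGG, TG-truster and UG-proposer roles the payoff consequences of
a choice depend on the co-player. The original study does not state what
participants assumed, so the package makes the assumption explicit in a
`belief_config()` shared by the forward simulator and the likelihood:
mid-grid contributions (JPY 500) for PDG and PGG partners, the break-even
expected return fraction 1/3 for the trustee, and a proposer who treats
offers as pure distributions (`pure_distribution`). An optional
`rejection_belief` mode instead weights each offer by the acceptance
probability of a softmax responder with configurable preferences, entering
the likelihood as expected utility. These are modelling conventions, not
claims about the original fit; any analysis must use the same beliefs in
simulation and estimation. The PGG reduces the n-player group to a single
representative other (all co-members assumed identical), the minimal
extension of the two-player utility.

## Priors

Defaults are weakly informative on the kJPY scale: α ~ Normal(0.8, 1),
β ~ Normal(0.4, 0.5), λ ~ half-Normal(0, 5). Signs of α and β are not
constrained, and the classic restrictions (β ≤ α, β < 1) are deliberately
not imposed: regularization lives entirely in the prior. The prior centres
and scales were chosen to cover published Fehr–Schmidt magnitudes (α
roughly 0–4, β roughly 0–1) while keeping mass off regions the design
cannot distinguish: the UG rejection threshold 750·α/(1+α) JPY saturates as
α grows, and giving behaviour in the DG and trustee role is essentially
constant in β well below 1, so a much flatter prior (e.g. sd 2) lets
posterior means wander into the saturated tails and inflates estimation
noise without adding information.

## Sampler and diagnostics

The sampler is a self-contained adaptive random-walk Metropolis on
(α, β, log λ): component-wise normal proposals whose scales adapt every 50
warmup iterations towards ~35% acceptance, then stay fixed; the half-normal
prior plus log-scale Jacobian keeps λ positive. Defaults run 4 chains of
2000 warmup + 2000 kept draws from dispersed prior starts. Convergence is
diagnosed with split-chain R-hat and an autocorrelation-based effective
sample size (Geyer initial positive/monotone truncation); a fit is flagged
(never dropped) when any R-hat exceeds 1.05 or any ESS falls below 200. All
randomness flows through R's RNG, so a seed makes fits bit-reproducible;
cohort fits derive per-participant child seeds from one master seed so
individuals can be re-fit independently.

As an independent check, `grid_posterior()` evaluates the pure-R likelihood
plus prior on a dense 3-D lattice (81 × 81 × 80 by default, spanning 3.5
prior sd, ≥ 99.9% prior mass) and normalizes. The bundled checks compare
MCMC and grid posterior means on three simulated participants at a 0.05
margin, using long chains (4 × 16000 kept) so Monte-Carlo error is well
below the margin.

## Genotype coding and association statistics

AVPR1A RS3 allele lengths are dichotomized at 330 bp (< 330 = S, ≥ 330 = L,
the sample-median convention), giving SS/SL/LL genotypes; the 334 bp allele
is tracked separately as carrier/non-carrier. Hardy–Weinberg equilibrium is
tested with the 1-df Pearson goodness-of-fit χ² without continuity
correction — the convention that reproduces the published cohort statistics
(0.075, 0.423, 0.756) from the printed genotype counts. Genotype
independence uses the standard 4-df Pearson test.

The association stage regresses each preference estimate (DIA, then AIA) on
the three genotype factors simultaneously plus an age covariate, with
sum-to-zero contrasts and Type-III (marginal) F tests — the SAS convention,
consistent with the published denominator df of 412 at n = 420 (n − 1 − 7).
Effect sizes are partial η² = SS/(SS + SS_error). Pairwise genotype
contrasts compare covariate-adjusted means (covariates at the grand mean,
other factors averaged), use the model error term, a per-comparison
Bonferroni threshold of 0.05/3 ≈ 0.017, and Cohen's d = adjusted-mean
difference / √MSE. Sex and sex-by-gene interactions are an optional flag,
as is replacing the RS3 factor by 334 bp carrier status. The whole stage is
verified against a from-scratch normal-equations oracle at 1e-8.

## The synthetic-study generator

`generate_study()` emulates the statistical structure of the genotyped
five-game cohort so every stage can be exercised without data access:

* **Genotypes** are drawn allele-wise (HWE by construction) at frequencies
  matching the observed genotype proportions: OXTR G ≈ 0.36, RS3 S ≈ 0.52,
  OPRM1 G ≈ 0.48, and 334 bp making up ≈ 0.42 of L alleles (which yields
  the observed ≈ 37% carrier rate). RS3 lengths are integers around the
  330 bp threshold so classification recovers the drawn class.
* **Ages** are Normal(41, 10.5) truncated to [20, 70], matching the cohort
  mean ± sd.
* **True preferences**: α ~ Normal(0.6, 0.4) truncated to [−0.5, 3], β ~
  Normal(0.4, 0.3) truncated to [−0.5, 2], λ ~ LogNormal(log 5, 0.4) kJPY⁻¹
  (or fixed). These are plausible-range simulation conventions, not
  estimates from the study. Age slopes default to values that reproduce the
  reported age–preference correlations (r ≈ 0.13 with DIA, 0.32 with AIA);
  genotype effects default to zero and are injected additively per effect
  allele (dominance codings can be emulated by supplying the factor
  directly to the association stage).
* **Choices** are drawn from the softmax forward model over the same
  37-context schedule and beliefs the fitting stage uses.

What the generator does *not* emulate: session/measurement-date structure,
income or cultural covariates, within-participant preference drift between
games, and any deviation from the softmax choice model itself. Passing
recovery and detection checks therefore validates the pipeline's internal
consistency, not the behavioural model's adequacy for real data.

### Calibrating an injected genotype effect

`rs3_effect_for_partial_eta2()` converts a target partial η² of the RS3
factor on *estimated* AIA (the scale on which association results are
reported) into the per-L-allele effect on true β. Posterior-mean estimates
are an attenuated, noisy image of the truth, so the conversion uses a
regression slope of estimate on truth of 0.75 and a measurement noise sd of
0.20 — both measured once from pilot estimation runs at the default design
(n = 420-scale cohorts, 37 decisions, the default priors, and the
2-chain × 800 + 800 sampler profile used for large simulation studies).
With the paper-scale target of 0.023 this yields a per-L-allele effect of
about 0.086 (SS − LL difference ≈ 0.17, Cohen's d ≈ 0.35 on the observed
scale, matching the reported contrast sizes).

## Numerical choices and degenerate inputs

* Softmax probabilities use max-subtraction, so λ·U up to ±700 cannot
  overflow; log-likelihoods are log-sum-exp based.
* `deterministic_choice()` breaks exact utility ties (within 1e-12) by the
  lexicographically lowest option label, for reproducibility.
* A monomorphic genotype sample yields HWE χ² = 0 with a warning rather
  than NaN; a constant dependent variable yields F = 0 (p = 1) for all
  ANCOVA terms; rank-deficient designs fail with the aliased columns named.
* Option grids are closed ranges (both endpoints included) in steps of JPY
  100, or 0.1 for trustee return fractions; validation rejects any choice
  off its grid with the offending row numbers.
* Cohort and study reproducibility: one master seed expands into per-stage
  (and per-participant) child seeds via R's RNG.

## Problem sizes of the bundled checks

The test suite and `scripts/acceptance.R` run entirely from simulated data:
3 participants for the MCMC/grid oracle comparison (4 × 16000 kept draws);
100 participants at λ = 5 for parameter recovery (default sampler); 500
replicates at n = 200 for the type-I error of the association stage
(computed on true parameters, isolating the ANCOVA); and 20 replicate
studies at n = 420 for end-to-end detection of an injected RS3 effect
(2 × 800 + 800 sampler profile). The detection bar — a significant AVPR1A
factor in at least 80% of replicates at observed partial η² = 0.023 — sits
essentially at the analytic power of that design (≈ 0.8), so individual
20-replicate runs fluctuate around it; the acceptance script reports the
realized rate alongside the false-positive rates of the untouched genes.

## Known limitations

* Information per participant is modest: 37 discrete decisions at λ ≈ 5
  kJPY⁻¹ leave posterior sds of ~0.5 for α and β — comparable to the
  between-person spread of the simulated truths — so truth–estimate
  correlations plateau around 0.7 at that noise level (they exceed 0.85 for
  near-deterministic λ = 20 agents). This is a property of the design, not
  of the sampler: the grid posterior shows the same spread.
* Estimation is per participant; no hierarchical pooling is attempted.
* The UG proposer's default likelihood ignores rejection risk
  (`pure_distribution`); `rejection_belief` is available but the believed
  responder's parameters must be supplied, not estimated.
* Beliefs about co-players are fixed configuration, not fitted quantities.
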