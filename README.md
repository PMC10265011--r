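# iafit — inequity-aversion estimation from economic games

`iafit` is an R package for researchers studying the biological and
behavioural basis of social preferences. It implements the full analysis
pipeline of a model-based candidate-gene study of inequity aversion:
estimate each participant's Fehr–Schmidt preferences from their behaviour
in five economic games, code candidate-gene genotypes, and test
gene–preference associations — plus a synthetic-study generator so the
whole pipeline is testable end to end without any data download.

## The model

Behaviour in the dictator (DG), prisoner's dilemma (PDG), public goods
(PGG), trust (TG) and ultimatum (UG) games is reduced to 37 decisions per
participant, each a choice among payoff allocations *(x, y)* for self and
other. Choices are modelled with the Fehr–Schmidt utility

> U(x, y) = x − α · max((x + y)/2 − x, 0) − β · max(x − (x + y)/2, 0)

where α is **disadvantageous inequity aversion** (DIA; disliking earning
less than the other) and β **advantageous inequity aversion** (AIA;
disliking earning more), combined with a softmax choice rule

> P(x′, y′) = exp(λ U(x′, y′)) / Σ exp(λ U(x, y))

with inverse temperature λ (0 = random, large = deterministic). The three
parameters are estimated per participant by MCMC (adaptive random-walk
Metropolis, split-chain R-hat and ESS diagnostics), with a dense-grid
posterior available as an independent oracle.

Downstream, the package codes OXTR rs53576 and OPRM1 rs1799971 genotypes
and AVPR1A RS3 microsatellite allele lengths (short/long at the 330 bp
median; 334 bp carrier status), tests Hardy–Weinberg equilibrium and
genotype independence, and runs the association ANCOVA: each preference
estimate on the three genes simultaneously with an age covariate, Type-III
F tests, partial η², and Bonferroni-corrected pairwise contrasts of
adjusted means (threshold 0.05/3 = 0.017, Cohen's d = Δ/√MSE).

## Worked example

```r
library(iafit)

# a complete synthetic study: genotypes, true preferences, game choices
study <- generate_study(simulation_config(n_participants = 60, seed = 7))

# fit one participant's 37 decisions
one <- subset(study$behaviour, participant_id == "P0001")
fit <- fit_participant(one, game_schedule(), config = mcmc_config(seed = 1))
fit
#> Inequity-aversion fit: 37 decisions, 4 chains x 2000 draws
#>   alpha (DIA)   0.616 (sd 0.367)
#>   beta  (AIA)   0.428 (sd 0.269)
#>   lambda        5.619 (sd 1.851)  [kJPY^-1]
#>   max R-hat 1.003, min ESS 695
study$truth[1, ]
#>  participant_id true_alpha true_beta true_lambda
#>           P0001      0.278     0.567        5.85
```

The posterior mean AIA (0.43, sd 0.27) sits close to the generating value
0.57; DIA is recovered with more uncertainty because only the 16
ultimatum-responder decisions are strongly informative about α. Whole
cohorts are fitted with `estimate_cohort()`, which returns one row of point
estimates and convergence diagnostics per participant.

```r
genotype_report(study$genotypes)
#> Genotype distribution (n = 60)
#>   OXTR    AA 36.7% (n = 22), AG 55.0% (n = 33), GG 8.3% (n = 5) | HWE chi2(1) = 2.305, p = 0.129
#>   AVPR1A  SS 21.7% (n = 13), SL 53.3% (n = 32), LL 25.0% (n = 15) | HWE chi2(1) = 0.276, p = 0.599
#>   OPRM1   AA 26.7% (n = 16), AG 53.3% (n = 32), GG 20.0% (n = 12) | HWE chi2(1) = 0.306, p = 0.580
#>   334 bp: non_carrier 61.7% (n = 37), carrier 38.3% (n = 23)
```

The association stage takes an estimates table and a genotype table:

```r
est   <- estimate_cohort(study$behaviour)            # one row per participant
assoc <- associate_preferences(est, study$genotypes) # ANCOVA + contrasts
assoc$anova                                          # F, df, p, partial eta^2
pairwise_bonferroni(assoc$fits$AIA, "avpr1a")        # adjusted-mean contrasts
```

The same stages run from a JSON/YAML config file via
`run_simulate()` / `run_fit()` / `run_associate()` / `run_report()`, or
from a shell through the thin wrapper `inst/scripts/ia-pipeline.R`.

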