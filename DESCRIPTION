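Package: iafit
Title: Inequity-Aversion Estimation from Economic Games and Genetic
    Association Testing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates Fehr-Schmidt inequity-aversion preferences
    (disadvantageous and advantageous inequity aversion plus softmax choice
    noise) from behaviour in five canonical economic games (dictator,
    prisoner's dilemma, public goods, trust and ultimatum games) by
    per-participant Bayesian inference with an adaptive random-walk
    Metropolis sampler. Also provides genotype coding for OXTR rs53576,
    AVPR1A RS3 microsatellite alleles and OPRM1 rs1799971, Hardy-Weinberg
    and genotype-independence tests, ANCOVA-based gene-preference
    association statistics with partial eta-squared effect sizes and
    Bonferroni-corrected pairwise contrasts, and a synthetic-study
    generator so the whole pipeline can be validated end to end without
    any behavioural data download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, graphics, tools, jsonlite, car, emmeans
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
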