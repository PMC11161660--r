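Package: ideatraj
Title: Continuous-Time Individual-Level Trajectory Models for Suicidal Ideation Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical continuous-time state-space models for irregularly
    observed, bounded ordinal symptom scores such as the summed SIDAS (0-50)
    suicidal-ideation scale. Latent Wiener or Ornstein-Uhlenbeck dynamics with
    exact transition densities are linked to the observed score through a
    scaled-logistic mean and a discretised normal distribution. Inference uses
    a bootstrap particle-filter likelihood inside a correlated pseudo-marginal
    Metropolis-Hastings-within-Gibbs sampler with semi-conjugate updates for
    the population-level random-effect distributions. Model variants are
    compared by WAIC, and fitted models produce 60-day posterior predictive
    trajectory bands together with clinical summaries: the integrated
    high-ideation probability (IHIP), future observational variability (V)
    and a recommended follow-up time (FUT). A synthetic-cohort generator
    emulating the sampling structure of digital measurement-based-care data
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
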