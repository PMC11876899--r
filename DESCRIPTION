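Package: rstddm
Title: Relative-Start-Time Drift Diffusion Modelling of Altruistic Choice
Version: 0.1.0
Authors@R: person("RSTDDM", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation, fitting and model comparison for a multi-attribute
    drift diffusion model in which the self-payoff and other-payoff
    attributes of a binary dictator-game choice may enter evidence
    accumulation at different onsets (relative start time, RST).  Provides a
    synthetic task-design and cohort generator emulating a dot-estimation
    social-status manipulation, a simulation-based likelihood maximised by
    differential evolution, random-effects Bayesian model selection with
    exceedance probabilities, parameter- and model-recovery harnesses, and
    model-free behavioural read-outs (decision betas, sliding-window betas,
    split-half cross-validation, social value orientation scoring, and
    bootstrap mediation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
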