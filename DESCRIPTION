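Package: pucddm
Title: Fixation-Gated Evidence-Accumulation Models of Value-Based Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fit, simulate and compare models of how eye fixations shape
    value-based binary choice. Implements the Posterior-Utility-Choice (PUC)
    model, in which an agent accumulates noisy value measurements gated by
    fixations, maintains a Gaussian posterior over each item's value, and
    derives utility as posterior mean minus an uncertainty-aversion penalty
    on the posterior standard deviation, together with the attentional
    drift-diffusion model (aDDM) and its collapsing-bound variant (acbDDM).
    The joint likelihood of choice and total fixation time is computed by
    numerical propagation of the decision-variable distribution with
    absorbing-boundary truncation; maximum-likelihood fitting uses
    multi-start derivative-free optimization on transformed parameters.
    Includes AICc/BIC model comparison with subject-level bootstrap
    confidence intervals, generative simulation, synthetic-experiment
    generation, parameter-recovery harnesses, and fixation-advantage
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    fitdistrplus,
    lhs
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
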