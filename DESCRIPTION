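Package: bayesubgroup
Title: Bayesian Treatment-Effect Estimation in Two Biomarker Subgroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian estimation of treatment effects in two disjoint
    biomarker-defined subgroups from published or trial-level summary
    estimates (for example log hazard ratios with confidence intervals).
    A bivariate normal approximation links the two subgroup estimators to
    the subgroup effects, and a menu of joint prior specifications
    expresses differing degrees of belief about the treatment-by-subgroup
    interaction: vague and informative normal priors, power priors that
    discount historical information, truncated priors, discrete priors,
    spike-and-slab mixtures, correlated bivariate normal priors, and a
    right-rectified-normal joint prior fitted by least squares to an
    elicited probability grid. Posteriors are computed in closed form
    where conjugate and otherwise by a bespoke Gibbs or
    Metropolis-within-Gibbs sampler. Trial-design utilities compute
    predicted event counts, posterior-predictive test statistics,
    Bayesian predictive power (assurance) and conditional power under
    gated sequential testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
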