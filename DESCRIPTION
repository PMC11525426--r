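Package: bfcheck
Title: Turing-Good Validation of Bayes Factor Computations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for checking that a Bayes factor implementation is computed
    correctly, using two classical moment identities: the expected Bayes factor
    in favor of the false hypothesis equals 1 (Turing), and the k-th raw moment
    of a Bayes factor under one hypothesis equals its (k+1)-st raw moment under
    the rival hypothesis (Good). Provides closed-form marginal likelihoods and
    Bayes factors for binomial tests with point, beta and truncated-beta
    (directional) priors, an exact enumeration oracle for Bayes factor moments,
    a JZS-style one-way ANOVA Bayes factor computed by quadrature over the g
    hyperprior, prior-predictive simulators, and a generic check engine that
    batches simulated Bayes factors, handles undefined values, and reports
    moment-based verdicts with Monte-Carlo standard errors, universal-bound
    diagnostics and weight-of-evidence summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
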