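Package: mitogerm
Title: Evolution of Germline Sequestration Under Mitochondrial Mutation and
    Segregational Drift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multilevel agent-based simulator of germline evolution driven by
    mitochondrial mutation and segregational drift. Cells carry populations of
    mutant and wild-type mitochondria that mutate, replicate and partition
    randomly at division; organisms develop from a zygote into tissues whose
    worst member sets adult fitness; finite populations of two mating types
    evolve nuclear modifier alleles controlling germline sequestration timing,
    germline proliferation and mitochondrial oogamy. An exact analytic
    distribution-propagation oracle (mutation and hypergeometric segregation
    transition matrices, closed-form segregational variance, oogamy variance
    recurrence) verifies the stochastic engine, and experiment drivers estimate
    modifier-allele fixation probabilities with binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
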