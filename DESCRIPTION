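Package: diplonar
Title: Negative Autoregulation in Diploids: Response Times, Noise and
    Binding-Site Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the expression dynamics and regulatory evolution of
    negatively autoregulating transcription factors in diploid cells, where
    the two alleles repress each other through a shared protein pool. Provides
    the two-allele ODE model with Hill repression and equilibrium solvers,
    perturbation/recovery response-time experiments and mutant-invasibility
    grids, a quasi-steady-state eigenvalue analysis with an under-dominance
    decomposition of the heterozygote relaxation rate, an exact stochastic
    simulator for intrinsic noise (Fano factors, stochastic response times),
    adaptive-walk simulations of autoregulatory binding-site evolution in
    haploids versus diploids under a thermodynamic mismatch energy model, and
    a synthetic regulatory-network census of autoregulation motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
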