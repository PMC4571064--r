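Package: lambdanet
Title: Multiple-Merger and Kingman Coalescent Gene Genealogies in Species
    Trees and Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates gene genealogies under the Kingman coalescent and two
    families of Lambda-coalescents (the psi point-mass coalescent derived from
    sweepstakes reproduction and the Beta(2-alpha,alpha)-coalescent) evolving
    inside rooted species trees and hybridization networks given in (extended)
    Newick format. Branch-specific coalescent parameters and effective
    population sizes are supported, with conversion between generations and
    coalescent units. Simulated genealogies can be decorated with
    infinite-sites mutations to produce 0/1 haplotype matrices, and summarised
    through gene-tree topology frequency tables, monophyly classification,
    the F_ST estimator based on average pairwise differences, and analytic
    low-mutation F_ST approximations for a two-population split model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
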