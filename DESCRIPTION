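Package: immunet
Title: Evolution of Constitutive and Induced Immune Defence in a
    Coevolving Signal-Transduction Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-based simulator of host-parasite coevolution in
    which each host carries a small immune signal-transduction network
    (a recognition receptor, a constitutively active protein and two
    effectors) encoded by bitstring sequences. Protein-protein
    interaction strengths are determined by Hamming-distance matching
    between input and output domains, network activities are obtained
    as steady states of an ordinary-differential-equation system, and
    host fitness trades the efficacy of constitutive and induced
    effector deployment against its expression cost under parasite
    counter-evolution. Provides the genome operations (mutation,
    between-protein recombination, matching-allele style specificity
    rules), a fast compiled coevolutionary loop with fitness-weighted
    lottery selection, per-generation summaries of effector activity,
    receptor detection, parasite diversity and evolved interaction
    strengths, and consensus-based divergence-rate diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
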