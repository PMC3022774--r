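Package: xenotract
Title: Molecular Forensics of Plant Mitochondrial Horizontal Gene Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the molecular-forensic analysis of horizontally
    transferred plant mitochondrial genes co-resident with native homologs:
    classification of gene copies as native or foreign by phylogenetic
    placement with bootstrap support and likelihood-based topology tests
    (Shimodaira-Hasegawa and approximately unbiased tests over RELL
    resampling of per-site GTR+Gamma+I log-likelihoods), detection of gene
    conversion tracts between xenologs by a permutation test on runs of
    phylogenetically informative sites, inference of DNA- versus RNA-mediated
    transfer from retention of cytidines at ancestral C-to-U RNA edit sites,
    Nei-Gojobori synonymous and non-synonymous divergence with Jukes-Cantor
    correction and codon-bootstrap standard errors, and localization of a
    locus to the mitochondrial, plastid or nuclear compartment from qPCR
    threshold-cycle panels. A synthetic-data generator simulates the full
    study design (species tree with a grafted transfer lineage,
    pseudogenization with frameshifting indels, implanted conversion tracts,
    edit-site states under either transfer mechanism, and three-genome qPCR
    copy-number structure) with a ground-truth ledger so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
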