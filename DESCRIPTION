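Package: ervclock
Title: Dating, Annotation and Phylogenetics of Endogenous Retrovirus Proviruses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to characterise families of endogenous retrovirus (ERV)
    proviral loci: majority-rule consensus building, LTR-divergence molecular
    clock dating with CpG masking, pairwise deletion and bootstrap dispersion,
    primer-binding-site (PBS) tRNA assignment, Betaretroviral protein motif
    scanning, A/T-rich stretch detection, chromosomal integration-site
    distribution statistics, and distance-based Neighbor-Joining phylogenetics
    with bootstrap bipartition support. Includes a provirus simulator with
    known ground truth (age, substitution counts, lesions, solo-LTR
    recombination products) so every analysis stage can be validated without
    external genome data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
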