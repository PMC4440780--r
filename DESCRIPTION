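Package: iscutrace
Title: Tracing Frataxin (CyaY) and Scaffold (IscU) Evolution Across Prokaryotic Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline for tracing the joint evolution of
    the bacterial frataxin homolog CyaY and the Fe-S cluster scaffold IscU.
    Builds column-wise log-odds profiles from seed alignments, scans proteomes
    with a glocal dynamic-programming aligner calibrated by empirical
    shuffled-decoy E-values, classifies U-family hits with a four-criterion
    acceptance rule (conserved cysteines, chaperone-recognition LPPVK motif,
    absence of extra domains, isc-operon gene neighborhood), takes a census of
    the residue at scaffold reference position 108 and computes sequence logos,
    profiles CyaY/IscU co-occurrence across genomes, reconstructs gain/loss
    histories on a species tree by Dollo and Fitch parsimony, and flags
    horizontal-transfer candidates by taxonomic incongruence in
    neighbor-joining gene trees. Includes a constrained simulator that emits
    miniature proteome corpora with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
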