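Package: mostwanted
Title: Prioritizing Unsequenced Taxa from 16S rRNA Amplicon Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of the analysis path used to build
    a sequencing-priority ("most wanted") list from 16S rRNA amplicon surveys
    of the human microbiome. Reads are clustered into consensus OTUs with a
    greedy abundance-ordered clusterer, consensus sequences are screened for
    two-parent (bimera) chimeras in reference and de novo modes, percent
    identity to tiered 16S reference collections is computed across affine-gap
    global alignments with free end gaps, per-body-site prevalence is derived
    from the OTU table, and each non-chimeric OTU is triaged into a high,
    medium, or low sequencing-priority class. A synthetic-community generator
    plants ground truth (source divergence, habitat-structured prevalence,
    skewed abundance, bimeric reads) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
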