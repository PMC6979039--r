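Package: mrascan
Title: Regulatory Network Inference, Master Regulator Analysis and Promoter Motif Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs transcription-factor regulatory networks from
    expression compendia by mutual information with data-processing-inequality
    pruning and a per-link permutation false discovery rate; scores each
    factor's regulon against a ranked differential-expression signature by
    GSEA-style enrichment with permutation p-values and normalized enrichment
    scores to call master regulators; and scans promoter sequences with
    position weight matrices, reporting normalized binding scores, exact
    dynamic-programming p-values and per-position q-values. A synthetic-data
    module plants networks, signatures and motif instances with known ground
    truth so every stage is testable end to end, and a pipeline layer
    intersects master regulators with promoter binders to shortlist direct
    regulators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    limma,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
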