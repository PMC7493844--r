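Package: cernet
Title: Inference of Competing Endogenous RNA Interactions from Paired
    Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A three-step pipeline for inferring competing endogenous RNA
    (ceRNA) interactions from paired miRNA and gene expression matrices and a
    miRNA-target interaction catalog. Candidate ceRNA pairs sharing a
    significant set of miRNAs are selected with a hypergeometric test, the
    supporting miRNA-target edges are filtered for significant negative
    expression correlation with a permutation-based global test, and the
    surviving pairs are scored with multiple sensitivity correlation (mscor,
    the drop from Pearson to partial correlation given the shared miRNAs)
    against a stratified empirical null distribution. Includes TSV readers and
    writers for expression matrices and interaction catalogs, a multi-tissue
    result store with query helpers, and a synthetic-data generator with
    planted sponge triplets and decoys so that every stage can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
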