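Package: oncophylo
Title: Multi-Site Tumor Relatedness, SCNA Phylogenies and Fusion-Pathway
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the genetic relatedness of multi-site tumors.
    Builds per-patient binary mutation matrices with deep-coverage rescue of
    low-VAF calls, classifies trunk/branch/private alterations, infers
    neighbor-joining phylogenies from hamming distances rooted at an all-zero
    germline, merges and encodes somatic copy-number segment profiles, calls
    recurrent gene-level SCNAs and integrates them with differential
    expression, and scores ranked gene lists against gene sets (GSEA, ssGSEA)
    with truncated-product p-value combination, ROC/AUC benchmarking, and
    drug-target prioritization. A seedable clonal-evolution simulator
    generates cohorts with known trunk/branch/private truth so every stage is
    testable without controlled-access data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    fgsea,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
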