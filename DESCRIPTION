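Package: gmpa
Title: Global Metal Protein Association Analysis for Metalloproteome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts metalloproteins from native chromatographic fractionation
    experiments in which metal concentrations per fraction are measured by ICP-MS
    and protein occurrences per fraction by tandem MS. Implements metal-peak region
    definition over fraction series, the hypergeometric Global Metal Protein
    Association (GMPA) score for protein/metal-peak co-occurrence, exponential
    significance-curve filtering anchored on known metalloproteins, hierarchical
    co-occurrence clustering with a dynamic hybrid tree cut to estimate
    metalloprotein counts, a greedy set-cover lower bound on those counts, a
    keyword-based InterPro metal-domain classifier, and a synthetic fractionation
    data generator with planted ground truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
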