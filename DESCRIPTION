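Package: secretodiff
Title: Differential Multiomics Analysis of Treatment-Conditioned Secretomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully testable pipeline for differential analysis of
    cell secretomes under drug treatment: scoring of membrane antibody
    cytokine arrays (duplicate-spot averaging, control-spot normalisation,
    floored intensities, differential metrics and hit counting), label-free
    proteomics differential-abundance statistics with the
    q-value/variability/fold-change filter cascade, count-based miRNA
    differential expression through trimmed-mean-of-M-values normalisation,
    precision-weight transformation and empirical-Bayes moderated
    t-statistics, overrepresentation and preranked running-sum gene-set
    enrichment, median-split Kaplan-Meier signature survival analysis, and
    expression-drug-response association. A synthetic-data module generates
    inputs with the statistical structure every stage assumes, with planted
    ground truth, so the whole pipeline is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    withr,
    optparse,
    fgsea
Config/testthat/edition: 3
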