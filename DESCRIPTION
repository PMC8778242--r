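Package: recscreen
Title: Expression-Reversal Drug Nomination with Recurrence Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end, fully synthetic-testable implementation of a
    gene-expression-reversal drug repositioning screen. Perturbation
    signatures over a panel of cancer cell lines are summarised per
    compound, gene and timepoint by a signed recurrence (REC) score with
    an exact or Monte-Carlo permutation p-value and Benjamini-Hochberg
    FDR; compounds are nominated by intersecting recurrent reversal of
    target genes with basal-expression versus drug-sensitivity
    correlations. Downstream stages cover preranked gene set enrichment
    analysis, Kaplan-Meier survival stratification with an expression
    cutoff scan and Bonferroni correction, mitochondrial morphology
    quantification from fluorescence micrographs, and four-parameter
    logistic IC50 estimation. A synthetic-data module generates every
    input format with planted effects so the whole pipeline is testable
    offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
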