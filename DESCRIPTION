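Package: pbfuse
Title: Integrated Metabolomic and Transcriptomic Analysis of Dose-Response
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint chemometric and transcriptomic analysis of
    designed dose-response studies, modelled on rodent phenobarbital
    exposure experiments. Provides NMR spectral bucketing with
    total-integral normalization and region renormalization, NIPALS
    partial least squares with Q2 cross-validation, Y-permutation
    validation and leave-out dose prediction, a microarray detection /
    fold-change / two-way ANOVA filtering cascade with
    Benjamini-Hochberg FDR control, hypergeometric pathway
    over-representation and pathway co-perturbation mapping,
    per-metabolite transcriptome PLS data fusion with a Q2-plus-permutation
    acceptance rule, one-way ANOVA with Dunnett many-to-one comparisons
    from raw data or printed summary statistics, lipid-species change
    tallies, and a synthetic-data generator that emulates a 4-dose by
    4-timepoint by 5-replicate study design with planted spectral,
    expression and gene-metabolite correlation effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mvtnorm,
    stats,
    tools,
    utils,
    withr
Suggests:
    mixOmics,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
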