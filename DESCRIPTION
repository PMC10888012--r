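Package: stabpath
Title: Protein Stability and Solvent Accessibility as Predictors of
    Missense Variant Pathogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking folding free energy change (ddG)
    and relative solvent accessibility (RSA) to the pathogenicity of
    missense variants in monogenic disorders. Provides curation filters
    for ClinVar-style variant tables (population frequency, clinical
    conflict, per-gene class balance), directed amino-acid substitution
    categorisation on four physicochemical axes, ddG sign-convention
    normalisation and ensemble averaging, cutoff-sweep ROC/AUC and
    Matthews-correlation threshold scans, balanced resampling assessment,
    an L2-penalised logistic classifier on (ddG, RSA) features with
    repeated cross-validated selection of the regularisation strength,
    a saturation-mutagenesis profiler, and a synthetic variant-table
    generator reproducing the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
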