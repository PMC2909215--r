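Package: membranome
Title: Comparative Membrane-Protein Gene Expression Analysis in Tumors and Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative expression analysis of the membranome, the set
    of genes encoding plasma-membrane proteins, across primary tumors, tumor-derived
    cell lines and normal tissues. Builds a membrane-gene catalog from annotation
    evidence (compartment terms, transmembrane and signal-peptide predictions,
    manual overrides); preprocesses multi-study expression compendia (replicate
    averaging, trimmed-mean scaling, quantile normalization, log2 transform);
    quantifies the classification power of gene pools by resampled nearest
    shrunken-centroid misclassification curves with exponential fits; compares
    tumors and cell lines by all-pairs Pearson correlation with cognate-tissue
    tests; identifies deregulated genes by a two-class permutation statistic with
    permutation-estimated false discovery rates; summarizes directional
    consistency of tumor deregulation in cell lines and cross-tissue overlap
    significance; performs Fisher-exact gene-set enrichment against GMT
    collections; and generates synthetic multi-study compendia with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
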