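Package: editpep
Title: Proteogenomic Screening and Quantitation of HLA Ligands from A-to-I RNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds edited-peptide search databases from A-to-I RNA editing
    sites, transcript models and a genome sequence; controls peptide
    identification error with a two-component score mixture (posterior error
    probabilities) and target-decoy false discovery rates; performs label-free
    relative quantitation and standard-curve based absolute quantitation of
    HLA-presented peptides in copies per cell; and computes tumour-association
    statistics (organ-grouped upper limit of normal, over-editing prevalence,
    editing levels from read pileups, Pearson correlations with Fisher-z
    intervals, logistic detection models). Ships a synthetic-data generator
    producing every input with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2
Config/testthat/edition: 3
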