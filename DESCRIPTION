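Package: seqfrust
Title: Sequence-Based Local Energetic Frustration for Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-residue local energetic frustration directly from
    a protein sequence by weighting a knowledge-based contact-potential
    table (Miyazawa-Jernigan) with evolutionary coupling scores and scanning
    all single-residue substitutions. Includes parsers for coupling-score
    files (plmc flat text and EVcouplings CSV) and Frustratometer mutational
    output, per-residue B-factor extraction from PDB files, benchmarking
    statistics (Spearman/Pearson correlation, quartile-labelled ROC and
    precision-recall analysis, paired comparisons, one-sided Wilcoxon
    signed-rank tests), a synthetic-instance generator with planted
    frustrated positions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
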