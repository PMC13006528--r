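Package: tagsite
Title: Scoring Proteins for Non-Disruptive Epitope-Tag Insertion Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts amino-acid positions where an epitope tag (e.g. V5) can
    be inserted into a protein with minimal risk of disrupting its function.
    Four per-residue features are combined: sequence conservation as
    normalized Shannon entropy over a multiple sequence alignment of
    vertebrate homologs, secondary-structure class and relative solvent
    accessibility derived from DSSP annotation of a predicted structure, and
    the complement of the ANCHOR2 disordered-binding propensity. Per-residue
    minimum-feature and weighted-sum scores are smoothed with a sliding
    window and candidate insertion sites are ranked. Includes parsers for the
    standard interchange formats (FASTA, PDB/mmCIF, DSSP, IUPred2A long
    output, BLAST tabular), a built-in Shrake-Rupley solvent-accessibility
    fallback, a synthetic fixture generator for offline testing, and a
    logistic-regression benchmark harness for labeled in-frame insertion
    variants with precision/recall/F1 reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
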