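Package: venomine
Title: Mining and Proteomic Validation of Cysteine-Rich Venom Toxins from EST Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A transcriptome-to-proteome discovery pipeline for cysteine-rich
    venom polypeptides. Expressed sequence tag (EST) reads are translated in
    six frames, open reading frames are mined for toxin precursors with a
    cysteine-spacing pattern language (single-residue distribution analysis),
    precursors are processed into candidate mature toxins (signal peptide,
    propeptide quadruplet cleavage, carboxypeptidase trimming, C-terminal
    amidation), toxins are organised into cysteine families and homology
    subfamilies, and predictions are validated against multi-protease
    peptide-spectrum-match tables via target-decoy FDR filtering, unique
    peptide mapping, sequence coverage and amidation evidence. A fully
    ground-truth-labelled synthetic data generator makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
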