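Package: pepminer
Title: Neuropeptide Precursor Annotation and Prohormone Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates neuropeptide prepropeptides from transcript or protein
    sequences: six-frame open reading frame translation, signal-peptide
    assignment (built-in hydropathy heuristic or imported external calls),
    prohormone convertase cleavage-site prediction with dibasic and monobasic
    rules, peptide excision with carboxypeptidase trimming, C-terminal
    amidation, pyroglutamate and sulfotyrosine inference, motif-based peptide
    family classification, structural typing of CHH-superfamily, insulin-like
    and CFSH precursors, and a hydropathy-based seven-transmembrane screen for
    candidate peptide GPCRs. Ships a synthetic-precursor generator with full
    ground truth so every stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
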