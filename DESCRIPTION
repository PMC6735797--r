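Package: proteolnc
Title: Proteogenomic Discovery of Proteins Encoded by Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering and characterizing proteins
    encoded by transcripts annotated as long non-coding RNAs. Detects
    translating lncRNAs from paired total-mRNA and translating-mRNA (RNC-seq)
    read counts, predicts canonical AUG-initiated open reading frames, builds
    cell-specific protein search databases and their low-molecular-weight
    subsets, adjudicates peptide evidence with a semi-global alignment filter
    using residue-equivalence classes (I/L, deamidation mass twins), applies
    transition-level verification rules for targeted mass spectrometry, and
    characterizes candidate proteins (isoelectric point, instability index,
    amino-acid class composition, in-silico trypsinolysis, iBAQ, near-AUG RNA
    folding energy, homology strata). A synthetic-data module generates
    transcriptomes, overdispersed count libraries, ribosome footprints,
    peptide identification lists and targeted-MS transition tables with known
    ground truth, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
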