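Package: circlpc
Title: Circular RNA Differential Classification and Biogenesis Features in
    LPC-Activated Endothelial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk-scale analysis of circular RNA (circRNA)
    induction in lysophosphatidylcholine (LPC)-activated human aortic
    endothelial cells: parsing of CIRCexplorer2- and CIRI-style back-splice
    junction tables, confidence-interval based significance filtering and
    six-group circRNA/mRNA classification, an exact binomial direction-bias
    test, reverse-complement flanking-intron homology scoring with
    Karlin-Altschul statistics, signed chromatin long-range interaction
    distance comparisons (Kolmogorov-Smirnov, Hodges-Lehmann,
    Fligner-Policello, Ansari-Bradley, Dwass-Steel-Critchlow-Fligner),
    and circular open reading frame, Kozak-motif and IRES characterisation.
    A seeded synthetic-data generator emulates every input so each stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
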