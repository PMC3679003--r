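Package: OpsinAssays
Title: Quantification of Opsin Photopigment Assays from Impedance and
    Patch-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying light responses of heterologously
    expressed opsin photopigments and of intrinsically photosensitive
    neurons. Implements the impedance-based (real-time cell analysis)
    light-response pipeline: cell-index normalization, baseline
    correction against light-insensitive control wells, area-under-curve
    light-response ratios, spectral normalization (%AUC), and response
    kinetics summaries; the patch-clamp windowed membrane-potential
    delta statistic with a dark-stability responsiveness classifier;
    exact small-sample Mann-Whitney and paired t tests; alignment-based
    annotation of opsin sequences (Schiff-base lysine and counterion
    positions in bovine rhodopsin numbering); and seeded synthetic-data
    generators for plate experiments and recording cohorts with the
    statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    deSolve,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
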