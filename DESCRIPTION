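Package: ppbscreen
Title: Candidate Calling for Isobaric-Tag Porphyrin-Probe Pulldown Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of multiplexed isobaric-tag (TMT)
    affinity-pulldown experiments that pool human and mouse cell lines with
    blank bead controls in a single plex. Implements reporter-ion isotope
    impurity correction, low-intensity PSM filtering, mean-centering,
    shared-peptide protein summarization and absolute scaling; a loading-bias
    normalization that uses cross-species-specific peptides as internal
    blanks; and an interaction-candidate statistic combining per-cell-line
    one-tailed t-tests against blanks by Fisher's method with
    Benjamini-Hochberg FDR control and a null-SD fold-change z gate. A
    synthetic-data generator with known ground truth makes every stage
    verifiable without raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
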