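Package: earbeat
Title: Ear-ECG Cardiac Rhythm Extraction and Channel Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the feasibility of electrocardiography from
    ear, scalp and neck electrodes against a standard Lead I reference.
    Synthesizes multichannel biopotential recordings from a dipole
    heart-vector source rendered through an analytic volume-conduction lead
    field, detects R-peaks with the Pan-Tompkins algorithm, extracts median
    cardiac rhythms by sliding ensemble medians over 600 ms beat windows,
    delineates the P-, Q-, R-, S- and T-waves, and scores candidate channels
    with four similarity metrics (Pearson correlation, wave amplitude ratio,
    wave timing error, normalized variance) across ensemble sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
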